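two_group_data <- function(k, n) {
  list(k = k, n = n, d = data.frame(flock = c("A", "B")))
}

test_that("saturated two-cell fit has closed-form coefficients", {
  d <- two_group_data(c(10L, 20L), c(100L, 100L))
  fit <- fit_binomial_glm(d$k, d$n, d$d, model_spec("flock"))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.10), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients[2]), qlogis(0.20) - qlogis(0.10),
               tolerance = 1e-7)
  expect_equal(fit$deviance, 0, tolerance = 1e-8)
})

test_that("identical groups give a null effect and P near 1", {
  d <- two_group_data(c(5L, 5L), c(100L, 100L))
  fit <- fit_binomial_glm(d$k, d$n, d$d, model_spec("flock"))
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-7)
  ft <- factor_test(fit, "flock")
  expect_equal(ft$statistic, 0, tolerance = 1e-8)
  expect_gt(ft$p_value, 0.999)
})

test_that("IRLS matches the reference fitter and a likelihood grid", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(50:400, 2)
    p <- runif(2, 0.02, 0.6)
    k <- rbinom(2, n, p)
    if (all(k == 0) || all(k == n)) next
    d <- data.frame(flock = c("A", "B"))
    fit <- fit_binomial_glm(k, n, d, model_spec("flock"))
    ref <- glm(cbind(k, n - k) ~ flock, data = d, family = binomial)
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(fit$deviance, deviance(ref), tolerance = 1e-6)
    if (!fit$separation) {
      expect_equal(fit$loglik, grid_loglik_two_group(k, n, d$flock),
                   tolerance = 1e-6)
    }
  }
})

test_that("IRLS log-likelihood trace is non-decreasing", {
  set.seed(11)
  for (rep in 1:20) {
    ncell <- sample(4:8, 1)
    d <- data.frame(flock = rep(c("A", "B"), length.out = ncell),
                    kind = rep(c("wall", "central"), each = 2,
                               length.out = ncell))
    n <- sample(100:2000, ncell, replace = TRUE)
    k <- rbinom(ncell, n, runif(1, 0.002, 0.2))
    if (all(k == 0)) next
    fit <- fit_binomial_glm(k, n, d, model_spec(c("flock", "kind")))
    expect_true(all(diff(fit$ll_trace) >= -1e-9))
  }
})

test_that("factor test is a likelihood-ratio chi-square and is invariant to
           reference level", {
  set.seed(5)
  d <- data.frame(flock = rep(c("A", "B", "C"), each = 2),
                  obs = rep(c("1", "2"), 3))
  n <- rep(1500L, 6)
  k <- rbinom(6, n, rep(c(0.008, 0.002, 0.02), each = 2))
  fit <- fit_binomial_glm(k, n, d, model_spec(c("flock", "obs")))
  ft <- factor_test(fit, "flock")
  # statistic equals twice the log-likelihood gap computed independently
  fit_red <- fit_binomial_glm(k, n, d, model_spec("obs"))
  expect_equal(ft$statistic, 2 * (fit$loglik - fit_red$loglik),
               tolerance = 1e-6)
  expect_identical(ft$df, 2L)
  # relabel so a different level sorts first: same statistic and P
  d2 <- d
  d2$flock <- c(A = "zzz", B = "mmm", C = "aaa")[d$flock]
  fit2 <- fit_binomial_glm(k, n, d2, model_spec(c("flock", "obs")))
  ft2 <- factor_test(fit2, "flock")
  expect_equal(ft2$statistic, ft$statistic, tolerance = 1e-6)
  expect_equal(ft2$p_value, ft$p_value, tolerance = 1e-6)
})

test_that("a strong simulated flock contrast is nearly always detected", {
  set.seed(202)
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    d <- data.frame(flock = c("A", "A", "B", "B"))
    n <- rep(2000L, 4)
    k <- rbinom(4, n, rep(c(0.008, 0.0003), each = 2))
    res <- tryCatch({
      fit <- fit_binomial_glm(k, n, d, model_spec("flock"))
      factor_test(fit, "flock")
    }, no_variation = function(e) NULL)
    if (!is.null(res) && isTRUE(res$estimable) && res$p_value < 0.001) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / reps, 0.95)
})

test_that("all-zero responses are refused with a no-variation condition", {
  d <- data.frame(flock = c("A", "B"))
  expect_error(fit_binomial_glm(c(0L, 0L), c(100L, 100L), d,
                                model_spec("flock")),
               class = "no_variation")
})

test_that("separation is flagged, rank deficiency errors with the column", {
  d <- data.frame(flock = c("A", "B"))
  fit <- fit_binomial_glm(c(0L, 50L), c(100L, 100L), d, model_spec("flock"))
  expect_true(fit$separation)
  d2 <- data.frame(flock = c("A", "A", "B", "B"),
                   copy = c("A", "A", "B", "B"))
  expect_error(
    fit_binomial_glm(c(5L, 6L, 10L, 12L), rep(100L, 4), d2,
                     model_spec(c("flock", "copy"))),
    "aliased")
})

test_that("Tukey with two levels equals the unadjusted test", {
  d <- data.frame(flock = rep(c("A", "B"), each = 3),
                  obs = rep(c("1", "2", "3"), 2))
  n <- rep(1000L, 6)
  k <- c(12L, 9L, 11L, 25L, 30L, 22L)
  fit <- fit_binomial_glm(k, n, d, model_spec(c("flock", "obs")))
  tk <- tukey_pairwise(fit, "flock")
  expect_identical(nrow(tk$comparisons), 1L)
  # equality up to the numerical accuracy of the studentized-range CDF
  expect_lt(abs(tk$comparisons$p_adjusted - tk$comparisons$p_unadjusted),
            1e-3)
})

test_that("Tukey adjustment never falls below the unadjusted P", {
  set.seed(33)
  for (rep in 1:15) {
    kk <- sample(3:5, 1)
    d <- data.frame(flock = rep(LETTERS[1:kk], each = 2),
                    obs = rep(c("1", "2"), kk))
    n <- sample(500:3000, 2 * kk, replace = TRUE)
    k <- rbinom(2 * kk, n, runif(kk, 0.005, 0.08)[rep(1:kk, each = 2)])
    if (all(k == 0)) next
    fit <- fit_binomial_glm(k, n, d, model_spec(c("flock", "obs")))
    if (fit$separation) next
    tk <- tukey_pairwise(fit, "flock")
    expect_true(all(tk$comparisons$p_adjusted >=
                    tk$comparisons$p_unadjusted - 1e-10))
    expect_true(all(tk$comparisons$p_adjusted <= 1))
  }
})

test_that("LS-means and Tukey tests agree with emmeans on a worked fit", {
  skip_if_not_installed("emmeans")
  d <- data.frame(flock = rep(c("A", "B", "C"), each = 2),
                  kind = rep(c("wall", "central"), 3),
                  k = c(14L, 9L, 30L, 25L, 4L, 7L),
                  n = c(1563L, 2188L, 2023L, 3447L, 1548L, 2202L))
  fit <- fit_binomial_glm(d$k, d$n, d, model_spec(c("flock", "kind")))
  ref <- glm(cbind(k, n - k) ~ flock + kind, data = d, family = binomial)
  # same residual df as ours (cells - parameters = 2) for comparability
  em <- emmeans::emmeans(ref, "flock", df = 2)
  em_sum <- as.data.frame(em)
  ours <- ls_means(fit, "flock")
  expect_equal(ours$lsmean_logit, em_sum$emmean, tolerance = 1e-5)
  expect_equal(ours$se_logit, em_sum$SE, tolerance = 1e-5)
  em_tk <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  tk <- tukey_pairwise(fit, "flock")
  expect_equal(abs(tk$comparisons$estimate), abs(em_tk$estimate),
               tolerance = 1e-5)
  expect_equal(tk$comparisons$p_adjusted, em_tk$p.value, tolerance = 1e-4)
})

test_that("equal LS-means share one letter; clear separation splits them", {
  d <- data.frame(flock = c("A", "B", "C"))
  fit_eq <- fit_binomial_glm(c(10L, 10L, 10L), rep(1000L, 3), d,
                             model_spec("flock"))
  tk <- suppressWarnings(tukey_pairwise(fit_eq, "flock"))
  expect_identical(unname(unique(tk$letters)), "a")
  fit_sep <- fit_binomial_glm(c(5L, 6L, 120L), rep(1000L, 3), d,
                              model_spec("flock"))
  tk2 <- suppressWarnings(tukey_pairwise(fit_sep, "flock"))
  expect_false(tk2$letters[["A"]] == tk2$letters[["C"]])
  expect_true(grepl(tk2$letters[["A"]], tk2$letters[["B"]], fixed = TRUE) ||
              tk2$letters[["A"]] == tk2$letters[["B"]])
})

test_that("spearman handles monotone transforms, reversals and ties", {
  x <- c(1, 3, 4, 7, 9, 15)
  expect_equal(spearman(x, x)$rho, 1)
  expect_equal(spearman(x, rev(x))$rho, -1)
  expect_equal(spearman(x, exp(x / 3))$rho, 1)  # strictly monotone transform
  res <- spearman(x, x^2)
  expect_equal(res$rho, 1)
  expect_equal(res$p_value, 0)
  const <- spearman(x, rep(2, 6))
  expect_false(const$defined)
  expect_true(is.na(const$rho))
})

test_that("tie-aware spearman matches a naive ranking oracle and cor.test", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(4:6, 1)
    x <- sample(1:4, n, replace = TRUE)   # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman(x, y)$rho, naive_spearman(x, y),
                 tolerance = 1e-12)
  }
  x <- c(2.1, 0.9, 3.1, 2.0, 4.4, 3.1)
  y <- c(0.9, 2.0, 1.6, 2.0, 2.0, 0.9)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(spearman(x, y)$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("method correlation matrices are symmetric with unit diagonal", {
  vals <- expand.grid(house_id = 1:6,
                      method = c("transect", "assurewel", "norwel"),
                      indicator = c("fl_head", "dirty"))
  set.seed(9)
  latent <- matrix(runif(12), 6)
  vals$value <- latent[cbind(vals$house_id,
                             as.integer(factor(vals$indicator)))] +
    rnorm(nrow(vals), 0, 0.05)
  mats <- method_correlation_matrix(vals)
  for (m in mats) {
    expect_equal(diag(m), setNames(rep(1, 3), rownames(m)))
    expect_equal(m, t(m))
    expect_true(all(m[!is.na(m)] >= -1 & m[!is.na(m)] <= 1))
  }
  # identical method vectors correlate perfectly
  vals2 <- vals[vals$indicator == "fl_head", ]
  vals2$value <- rep(latent[, 1], 3)
  m2 <- method_correlation_matrix(vals2)[["fl_head"]]
  expect_true(all(m2 == 1))
  # too few flocks: entry omitted with a reason
  m3 <- method_correlation_matrix(vals2[vals2$house_id <= 2, ])[["fl_head"]]
  expect_true(all(is.na(m3[upper.tri(m3)])))
  expect_match(attr(m3, "skipped"), "complete flock", all = FALSE)
})

test_that("shared latent severity drives mean between-method correlation up", {
  set.seed(404)
  mean_rho <- function(sigma) {
    rhos <- replicate(40, {
      latent <- runif(6)
      vals <- expand.grid(house_id = 1:6,
                          method = c("m1", "m2", "m3"))
      vals$indicator <- "fl_head"
      vals$value <- latent[vals$house_id] + rnorm(18, 0, sigma)
      m <- method_correlation_matrix(vals)[["fl_head"]]
      mean(m[upper.tri(m)])
    })
    mean(rhos)
  }
  expect_gt(mean_rho(0.02), mean_rho(0.5))
})
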