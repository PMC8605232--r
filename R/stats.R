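#' Model specification for a binomial prevalence comparison
#'
#' Declares which fixed factors enter the logit model for one indicator.
#' Factors with fewer than two observed levels are dropped with a warning at
#' fit time; the first level by sort order is the reference (results are
#' invariant to this choice).
#'
#' @param factors Character vector, ordered subset of
#'   `c("flock", "observer", "transect_kind", "vertical_level")` (any
#'   column names present in the data are accepted).
#' @return A `model_spec` object.
#' @export
model_spec <- function(factors) {
  stopifnot(is.character(factors), length(factors) >= 1L)
  structure(list(factors = factors), class = "model_spec")
}

binom_loglik <- function(k, n, mu) {
  sum(stats::dbinom(k, n, mu, log = TRUE))
}

#' Fit a fixed-effects binomial logit model by IRLS
#'
#' Fits `cbind(successes, trials - successes) ~ factors` with a logit link
#' by iteratively reweighted least squares with step halving, so the
#' log-likelihood is non-decreasing across iterations.  Convergence is
#' declared when the largest coefficient change falls below `1e-8`
#' (at most 100 iterations).  Quasi-complete separation is flagged when any
#' coefficient exceeds 10 on the logit scale at convergence; such fits carry
#' `separation = TRUE` and their contrasts are treated as non-estimable.
#' A response with no variation (all zero or all saturated) is refused with
#' a `no variation` condition so callers can report it descriptively.
#'
#' @param successes Integer vector of indicator-positive birds per cell.
#' @param trials Integer vector of birds at risk per cell (estimated birds
#'   in the transect, or birds sampled).
#' @param data Data frame holding the factor columns, one row per cell.
#' @param spec A [model_spec()].
#' @return A `binom_glm_fit`: coefficients (logit scale), covariance matrix,
#'   deviance, log-likelihood, residual df, convergence and separation flags,
#'   fitted probabilities, iteration log-likelihood trace, and the design
#'   information needed for LS-means.
#' @export
fit_binomial_glm <- function(successes, trials, data, spec) {
  stopifnot(length(successes) == length(trials),
            nrow(data) == length(successes),
            all(successes >= 0), all(trials >= 1),
            all(successes <= trials))
  k <- as.numeric(successes); n <- as.numeric(trials)
  if (all(k == 0) || all(k == n)) {
    cond <- structure(
      class = c("no_variation", "error", "condition"),
      list(message = "response has no variation; nothing to model",
           call = sys.call(-1)))
    stop(cond)
  }
  factors <- spec$factors
  keep <- vapply(factors, function(f) {
    nl <- length(unique(data[[f]]))
    if (nl < 2L) warning("factor '", f, "' has < 2 observed levels; dropped")
    nl >= 2L
  }, logical(1))
  factors <- factors[keep]
  for (f in factors) data[[f]] <- factor(data[[f]])
  form <- if (length(factors)) {
    stats::as.formula(paste("~", paste(factors, collapse = " + ")))
  } else stats::as.formula("~ 1")
  X <- stats::model.matrix(form, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  # IRLS with step halving: guarantees a monotone log-likelihood trace
  beta <- rep(0, ncol(X))
  beta[1] <- stats::qlogis(min(max(sum(k) / sum(n), 1e-6), 1 - 1e-6))
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- binom_loglik(k, n, mu)
  ll_trace <- ll
  converged <- FALSE
  for (it in seq_len(100L)) {
    w <- n * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (k - n * mu) / w
    fit_wls <- stats::lm.wfit(X, z, w)
    beta_new <- fit_wls$coefficients
    step <- beta_new - beta
    ll_new <- -Inf
    for (h in 0:30) {
      cand <- beta + step / 2^h
      mu_c <- stats::plogis(drop(X %*% cand))
      ll_c <- binom_loglik(k, n, mu_c)
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) {
        beta_new <- cand; ll_new <- ll_c; break
      }
    }
    if (!is.finite(ll_new)) break
    delta <- max(abs(beta_new - beta))
    ll_gain <- ll_new - ll
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    # coefficient convergence, or likelihood convergence: under separation
    # the coefficients drift forever while the likelihood (and deviance)
    # settle, and the deviance-based tests remain well defined
    if (delta < 1e-8 || ll_gain < 1e-10) { converged <- TRUE; break }
  }

  w <- pmax(n * mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X, X * w)
  vcov <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X),
           dimnames = list(colnames(X), colnames(X)))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  mu_sat <- ifelse(n > 0, k / n, 0)
  ll_sat <- binom_loglik(k, n, pmin(pmax(mu_sat, 1e-12), 1 - 1e-12))
  deviance <- 2 * (ll_sat - ll)
  separation <- any(abs(beta) > 10)

  fit <- list(coefficients = beta, vcov = vcov,
              deviance = max(deviance, 0), loglik = ll,
              df_residual = length(k) - ncol(X),
              converged = converged, separation = separation,
              fitted = mu, ll_trace = ll_trace,
              successes = k, trials = n,
              factors = factors,
              factor_levels = lapply(stats::setNames(factors, factors),
                                     function(f) levels(data[[f]])),
              X = X, data = data, formula = form)
  class(fit) <- "binom_glm_fit"
  fit
}

#' @export
print.binom_glm_fit <- function(x, ...) {
  cat(sprintf("<binom_glm_fit> %s cells, deviance %.3f on %d df%s%s\n",
              length(x$successes), x$deviance, x$df_residual,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [separation]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test for one fixed factor
#'
#' Compares the fitted model with the model omitting `factor` by the
#' likelihood-ratio chi-square: statistic = deviance(reduced) −
#' deviance(full) = 2 (loglik(full) − loglik(reduced)), on levels − 1
#' degrees of freedom.
#'
#' @param fit A converged [fit_binomial_glm()] result.
#' @param factor Name of a factor in the fit.
#' @return List: `statistic`, `df`, `p_value`, `estimable`.  When either
#'   model failed to converge the P value is `NA` with `estimable = FALSE`.
#' @export
factor_test <- function(fit, factor) {
  stopifnot(inherits(fit, "binom_glm_fit"))
  if (!factor %in% fit$factors) {
    stop("factor '", factor, "' not in fitted model", call. = FALSE)
  }
  reduced_factors <- setdiff(fit$factors, factor)
  fit_r <- if (length(reduced_factors)) {
    fit_binomial_glm(fit$successes, fit$trials, fit$data,
                     model_spec(reduced_factors))
  } else {
    fit_intercept_only(fit$successes, fit$trials, fit$data)
  }
  if (!fit$converged || !fit_r$converged) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                estimable = FALSE))
  }
  stat <- max(fit_r$deviance - fit$deviance, 0)
  df <- length(fit$factor_levels[[factor]]) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       estimable = TRUE)
}

# intercept-only fit, used as the reduced model for single-factor specs
fit_intercept_only <- function(k, n, data) {
  phat <- sum(k) / sum(n)
  mu <- rep(min(max(phat, 1e-12), 1 - 1e-12), length(k))
  ll <- binom_loglik(k, n, mu)
  mu_sat <- pmin(pmax(k / n, 1e-12), 1 - 1e-12)
  ll_sat <- binom_loglik(k, n, mu_sat)
  list(deviance = 2 * (ll_sat - ll), loglik = ll, converged = TRUE)
}

# contrast row giving the LS-mean of one level of one factor: that level's
# dummy set, every other factor averaged uniformly over its levels
lsmean_contrast <- function(fit, factor, level) {
  cn <- colnames(fit$X)
  L <- stats::setNames(numeric(length(cn)), cn)
  L["(Intercept)"] <- 1
  for (f in fit$factors) {
    lev <- fit$factor_levels[[f]]
    cols <- paste0(f, lev[-1L])
    if (f == factor) {
      if (level != lev[1L]) L[paste0(f, level)] <- 1
    } else {
      L[cols] <- 1 / length(lev)
    }
  }
  L
}

#' LS-means of a fitted factor
#'
#' Model-based marginal means on the logit scale (other factors averaged
#' uniformly over their levels), back-transformed to the response scale.
#'
#' @inheritParams factor_test
#' @return Data frame: `level`, `lsmean_logit`, `se_logit`, `lsmean_p`
#'   (percent).
#' @export
ls_means <- function(fit, factor) {
  stopifnot(inherits(fit, "binom_glm_fit"), factor %in% fit$factors)
  lev <- fit$factor_levels[[factor]]
  out <- do.call(rbind, lapply(lev, function(l) {
    L <- lsmean_contrast(fit, factor, l)
    est <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    data.frame(level = l, lsmean_logit = est, se_logit = se,
               lsmean_p = 100 * stats::plogis(est),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tukey-adjusted pairwise comparisons of LS-means
#'
#' All `k (k - 1) / 2` pairwise differences of a factor's LS-means on the
#' logit scale.  Adjusted P values come from the studentized-range
#' distribution with residual df = cells − parameters; when that df is not
#' positive the normal reference (infinite df) is used with a warning.
#' A compact letter display at `alpha` is attached: levels sharing a letter
#' are not significantly different.
#'
#' @inheritParams factor_test
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `comparisons` (data frame: pair, `estimate` logit
#'   difference, `se`, `t`, `p_unadjusted`, `p_adjusted`) and `letters`
#'   (named character vector per level).
#' @export
tukey_pairwise <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "binom_glm_fit"), factor %in% fit$factors)
  if (!fit$converged) stop("model did not converge", call. = FALSE)
  lsm <- ls_means(fit, factor)
  kk <- nrow(lsm)
  if (kk < 2L) stop("factor needs at least 2 levels", call. = FALSE)
  df <- fit$df_residual
  if (df <= 0) {
    warning("residual df <= 0; using normal (infinite-df) reference")
    df <- Inf
  }
  pairs <- utils::combn(seq_len(kk), 2)
  comp <- do.call(rbind, apply(pairs, 2, function(idx) {
    i <- idx[1]; j <- idx[2]
    Li <- lsmean_contrast(fit, factor, lsm$level[i])
    Lj <- lsmean_contrast(fit, factor, lsm$level[j])
    d <- Li - Lj
    est <- sum(d * fit$coefficients)
    se <- sqrt(drop(t(d) %*% fit$vcov %*% d))
    tval <- est / se
    p_un <- if (is.finite(df)) 2 * stats::pt(-abs(tval), df)
            else 2 * stats::pnorm(-abs(tval))
    p_adj <- stats::ptukey(abs(tval) * sqrt(2), nmeans = kk,
                           df = if (is.finite(df)) df else 1e7,
                           lower.tail = FALSE)
    data.frame(level_1 = lsm$level[i], level_2 = lsm$level[j],
               estimate = est, se = se, t = tval,
               p_unadjusted = p_un, p_adjusted = p_adj,
               stringsAsFactors = FALSE)
  }))
  rownames(comp) <- NULL
  letters_cld <- compact_letters(lsm$level, lsm$lsmean_logit, comp, alpha)
  list(comparisons = comp, letters = letters_cld, alpha = alpha)
}

# greedy insertion compact letter display: walk levels sorted by LS-mean,
# start a new letter group whenever a significant pair breaks the current
# one; ties in the sort broken by level order
compact_letters <- function(levels, means, comparisons, alpha) {
  ord <- order(means, levels)
  lev_sorted <- levels[ord]
  sig <- function(a, b) {
    row <- comparisons[(comparisons$level_1 == a & comparisons$level_2 == b) |
                       (comparisons$level_1 == b & comparisons$level_2 == a), ]
    nrow(row) > 0 && !is.na(row$p_adjusted[1]) && row$p_adjusted[1] < alpha
  }
  groups <- list()  # each: character vector of member levels
  for (lv in lev_sorted) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(vapply(groups[[gi]], sig, logical(1), b = lv))) {
        groups[[gi]] <- c(groups[[gi]], lv)
        placed <- TRUE
      }
    }
    if (!placed) {
      # seed a new group: lv plus earlier levels mutually compatible with it
      grp <- lv
      for (prev in lev_sorted[seq_len(match(lv, lev_sorted) - 1L)]) {
        if (!any(vapply(grp, sig, logical(1), b = prev))) grp <- c(grp, prev)
      }
      groups[[length(groups) + 1L]] <- grp
    }
  }
  if (!length(groups)) groups <- list(lev_sorted)
  # absorb redundant groups (subsets of another)
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i != j && keep[j] && all(groups[[i]] %in% groups[[j]]) &&
          length(groups[[i]]) < length(groups[[j]])) keep[i] <- FALSE
    }
  }
  groups <- groups[keep]
  out <- stats::setNames(rep("", length(levels)), levels)
  for (gi in seq_along(groups)) {
    for (lv in groups[[gi]]) out[lv] <- paste0(out[lv], letters[gi])
  }
  out[order(names(out))]
}

#' Spearman rank correlation with average ranks for ties
#'
#' Assigns average ranks to ties in each vector, computes the Pearson
#' correlation of the ranks, and tests it with the t approximation on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (`n >= 3`); pairs with a
#'   missing value in either vector are removed first.
#' @return List: `rho`, `p_value`, `n`, `defined`.  When either vector has
#'   zero rank variance `rho` is `NA` and `defined = FALSE`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p_value = p, n = n, defined = TRUE)
}

#' Between-method correlation matrix for comparable indicators
#'
#' For each indicator that all assessment methods measure on a comparable
#' definition (e.g. feather loss on the head as a bare patch over 5 cm),
#' computes the Spearman correlation between every pair of methods across
#' flock-level values.
#'
#' @param values Data frame with columns `house_id`, `method`, `indicator`,
#'   `value` (one flock-level summary per method and indicator).
#' @param min_flocks Minimum number of complete flocks per method pair
#'   (default 3); pairs below it are `NA` with a reason recorded.
#' @return Named list of symmetric correlation matrices (one per indicator,
#'   diagonal 1) with attributes `p_values` (matrix) and `skipped`
#'   (character vector of omitted entries and reasons).
#' @export
method_correlation_matrix <- function(values, min_flocks = 3L) {
  stopifnot(all(c("house_id", "method", "indicator", "value") %in%
                names(values)))
  out <- list()
  for (ind in unique(values$indicator)) {
    d <- values[values$indicator == ind, ]
    wide <- stats::reshape(d[, c("house_id", "method", "value")],
                           idvar = "house_id", timevar = "method",
                           direction = "wide")
    methods <- sub("^value\\.", "", names(wide)[-1L])
    m <- matrix(NA_real_, length(methods), length(methods),
                dimnames = list(methods, methods))
    pm <- m
    skipped <- character(0)
    diag(m) <- 1
    for (i in seq_along(methods)) for (j in seq_along(methods)) {
      if (j <= i) next
      xi <- wide[[i + 1L]]; xj <- wide[[j + 1L]]
      ok <- stats::complete.cases(xi, xj)
      if (sum(ok) < min_flocks) {
        skipped <- c(skipped, sprintf(
          "%s: %s vs %s: only %d complete flock(s)", ind,
          methods[i], methods[j], sum(ok)))
        next
      }
      sp <- spearman(xi[ok], xj[ok])
      m[i, j] <- m[j, i] <- sp$rho
      pm[i, j] <- pm[j, i] <- sp$p_value
    }
    attr(m, "p_values") <- pm
    attr(m, "skipped") <- skipped
    out[[ind]] <- m
  }
  out
}
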