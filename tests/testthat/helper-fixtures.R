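# Shared fixtures and independent oracles, built in code.

# The six field-study houses (measured aisle widths left->right, house width,
# structure rows, flock size, usable area).  House 2's aisles are the closest
# reading of an ambiguous source and are excluded from golden checks.
study_houses <- function() {
  list(
    `1` = house_geometry(1, 14.0, c(1.75, 1.75, 1.75, 1.75), 3, 7500, 1850,
                         floor_area = 1000),
    `2` = house_geometry(2, 12.0, c(1.54, 1.51, 1.51, 1.54), 3, 7700, 990,
                         floor_area = 506),
    `3` = house_geometry(3, 11.0, c(1.11, 1.11, 1.11), 2, 7840, 915,
                         floor_area = 432),
    `4` = house_geometry(4, 10.0, c(2.11, 2.11), 1, 7200, 815,
                         floor_area = 385),
    `5` = house_geometry(5, 12.0, c(1.03, 1.10, 1.04), 2, 7500, 1005,
                         floor_area = 648),
    `6` = house_geometry(6, 11.0, c(1.40, 1.49, 1.49, 1.40), 3, 7500, 910,
                         floor_area = 450))
}

# Published per-transect bird tallies (golden cells; house 2 excluded).
study_bird_tallies <- function() {
  list(`1` = c(1563, 2188, 2188, 1563),
       `3` = c(2158, 3524, 2158),
       `4` = c(3600, 3600),
       `5` = c(2023, 3447, 2030),
       `6` = c(1548, 2202, 2202, 1548))
}

# Published usable-area densities (birds/m2, truncated to 2 decimals).
study_densities <- function() {
  c(`1` = 4.05, `2` = 7.77, `3` = 8.56, `4` = 8.83, `5` = 7.46, `6` = 8.24)
}

# Rounded structure widths from the field report, for the 0.01 m cross-check.
study_structure_widths <- function() {
  c(`1` = 2.33, `2` = 1.96, `3` = 3.83, `4` = 5.78, `5` = 4.41, `6` = 1.74)
}

extdata <- function(name) {
  system.file("extdata", name, package = "aviarytransect", mustWork = TRUE)
}

# Rebuild per-bird 50-bird-scheme records from a published prevalence row
# set: k birds at each score level, the rest 0.
bird_records_from_prevalence <- function(prev_rows, house_id, n = 50) {
  codes <- unique(prev_rows$indicator)
  scores <- matrix(0L, nrow = n, ncol = length(codes),
                   dimnames = list(NULL, codes))
  for (code in codes) {
    rows <- prev_rows[prev_rows$indicator == code, ]
    pos <- 1L
    for (i in seq_len(nrow(rows))) {
      k <- as.integer(round(rows$p[i] * n / 100))
      if (k > 0) {
        scores[pos:(pos + k - 1L), code] <- as.integer(rows$score_level[i])
        pos <- pos + k
      }
    }
  }
  cbind(data.frame(house_id = house_id, scheme = "assurewel",
                   bird_ordinal = seq_len(n)),
        as.data.frame(scores))
}

random_valid_geometry <- function() {
  n_str <- sample(1:3, 1)
  aisles <- round(stats::runif(n_str + 1, 0.8, 2.5), 2)
  sw <- stats::runif(1, 1, 6)
  house_geometry(paste0("rg", sample.int(1e6, 1)),
                 house_width = sum(aisles) + n_str * sw,
                 aisle_widths = aisles, n_structures = n_str,
                 flock_size = sample(2000:9000, 1),
                 usable_area = stats::runif(1, 400, 2000))
}

# --- independent oracles ---------------------------------------------------

# Spearman by explicit average-rank construction (no rank()/cor() shortcuts
# beyond the arithmetic definition).
naive_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Maximised binomial log-likelihood by direct grid search over cell means,
# exploiting that a full-rank factor model on <= 4 cells either saturates
# the cells it distinguishes or pools cells sharing a factor pattern.
grid_loglik_two_group <- function(k, n, group) {
  # common logit grid over intercept and group effect, refined twice
  best <- -Inf
  b0 <- seq(-8, 8, length.out = 161); b1 <- seq(-8, 8, length.out = 161)
  for (pass in 1:3) {
    ll <- outer(b0, b1, Vectorize(function(a, b) {
      mu <- plogis(a + b * (group == levels(factor(group))[2]))
      sum(dbinom(k, n, mu, log = TRUE))
    }))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- max(ll)
    w0 <- diff(b0[1:2]) * 2; w1 <- diff(b1[1:2]) * 2
    b0 <- seq(b0[idx[1]] - w0, b0[idx[1]] + w0, length.out = 81)
    b1 <- seq(b1[idx[2]] - w1, b1[idx[2]] + w1, length.out = 81)
  }
  best
}
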