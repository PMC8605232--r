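#' Simulation configuration for a synthetic flock
#'
#' Bundles everything needed to generate one flock and its observation
#' process: the house geometry, per-indicator true prevalences, a wall
#' placement bias for affected birds, the vertical distribution of birds,
#' an observer detection model, and the graded-scheme sample size.
#'
#' `wall_bias` is the relative risk that an affected bird resides in a wall
#' transect rather than a central one (1 = affected birds distributed like
#' the rest of the flock); it lets the simulator reproduce the pattern of
#' more affected birds near the walls.  Unaffected birds are always placed
#' proportionally to transect width.
#'
#' @param geometry A valid [house_geometry()].
#' @param prevalence Named numeric vector of true per-indicator prevalences
#'   as fractions in `[0, 1]` (names are indicator codes).
#' @param wall_bias Positive relative risk of wall placement for affected
#'   birds; default 1 (homogeneous).
#' @param vertical_weights Probability vector over the vertical levels
#'   (litter, 1st, 2nd, top tier); default uniform over 4 levels.
#' @param sensitivity Probability an affected bird is tallied during a
#'   transect walk (default 1).
#' @param fp_rate Probability an unaffected bird is wrongly tallied
#'   (default 0).
#' @param sample_n Birds per graded-scheme sample (default 50).
#' @param severity_p2 Probability an affected bird sampled under a graded
#'   scheme presents as major (score 2) rather than minor (score 1);
#'   default 0.5.  Never affects transect counts.
#' @param seed Integer seed; every operation derives its own independent
#'   stream from `(seed, operation name)`, so adding operations never
#'   perturbs existing draws.
#' @return A `sim_config` object.
#' @export
sim_config <- function(geometry, prevalence, wall_bias = 1,
                       vertical_weights = rep(0.25, 4),
                       sensitivity = 1, fp_rate = 0,
                       sample_n = 50L, severity_p2 = 0.5, seed = 1L) {
  assert_valid_geometry(geometry)
  stopifnot(is.numeric(prevalence), !is.null(names(prevalence)),
            all(prevalence >= 0 & prevalence <= 1),
            wall_bias > 0,
            abs(sum(vertical_weights) - 1) < 1e-9,
            all(vertical_weights >= 0),
            sensitivity >= 0, sensitivity <= 1,
            fp_rate >= 0, fp_rate <= 1,
            sample_n >= 1, sample_n <= geometry$flock_size,
            severity_p2 >= 0, severity_p2 <= 1)
  structure(list(geometry = geometry, prevalence = prevalence,
                 wall_bias = wall_bias,
                 vertical_weights = vertical_weights,
                 sensitivity = sensitivity, fp_rate = fp_rate,
                 sample_n = as.integer(sample_n),
                 severity_p2 = severity_p2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# derive an operation-specific RNG seed below 2^31 from the global seed and
# the operation name, so streams are independent and order-insensitive
op_seed <- function(seed, op) {
  ch <- utf8ToInt(op)
  h <- 0
  for (c in ch) h <- (h * 131 + c) %% 2147483647
  as.integer(((abs(seed) %% 2147483647) * 16807 + h) %% 2147483647)
}

with_op_seed <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(op_seed(seed, op))
  expr
}

#' Simulate one flock with ground-truth indicator states
#'
#' Places every bird in a transect (multinomial with weights proportional to
#' transect width, times `wall_bias` for affected birds in wall transects)
#' and a vertical level, and assigns each indicator independently per bird
#' as a Bernoulli draw at its true prevalence (multi-label: a bird may carry
#' several indicators).
#'
#' @param config A [sim_config()].
#' @return A `simulated_flock`: data frame with one row per bird
#'   (`bird_id`, `transect_index`, `transect_kind`, `vertical_level`, one
#'   logical column per indicator), with the layout and config attached as
#'   attributes.
#' @export
simulate_flock <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$geometry
  layout <- estimate_birds_per_transect(g)
  nb <- g$flock_size
  codes <- names(config$prevalence)
  with_op_seed(config$seed, "simulate_flock", {
    affected <- vapply(codes, function(code) {
      stats::runif(nb) < config$prevalence[[code]]
    }, logical(nb))
    if (nb == 1L) affected <- matrix(affected, nrow = 1L,
                                     dimnames = list(NULL, codes))
    any_affected <- if (length(codes)) rowSums(affected) > 0 else
      rep(FALSE, nb)
    w_plain <- layout$width
    w_bias <- layout$width *
      ifelse(layout$kind == "wall", config$wall_bias, 1)
    transect <- integer(nb)
    n_plain <- sum(!any_affected)
    if (n_plain) transect[!any_affected] <- sample(layout$index, n_plain,
                                                   replace = TRUE,
                                                   prob = w_plain)
    n_aff <- sum(any_affected)
    if (n_aff) transect[any_affected] <- sample(layout$index, n_aff,
                                                replace = TRUE,
                                                prob = w_bias)
    nlev <- length(config$vertical_weights)
    vlevel <- sample(seq_len(nlev), nb, replace = TRUE,
                     prob = config$vertical_weights)
    flock <- data.frame(bird_id = seq_len(nb),
                        transect_index = transect,
                        transect_kind = layout$kind[match(transect,
                                                          layout$index)],
                        vertical_level = vlevel,
                        stringsAsFactors = FALSE)
    for (code in codes) flock[[code]] <- affected[, code]
    attr(flock, "layout") <- layout
    attr(flock, "config") <- config
    class(flock) <- c("simulated_flock", "data.frame")
    flock
  })
}

#' Simulate transect-walk observation of a flock
#'
#' For each transect, observer and indicator, the tally is a binomial draw:
#' affected birds present are each detected with probability `sensitivity`,
#' and each unaffected bird contributes a false positive with probability
#' `fp_rate`.  Observers draw independently.
#'
#' @param flock A [simulate_flock()] result.
#' @param config The [sim_config()] used (defaults to the one attached to
#'   the flock).
#' @param n_observers Number of independent observers (default 2).
#' @return Data frame in the transect-count schema: `house_id`,
#'   `observer_id`, `transect_index`, plus one count column per indicator.
#' @export
observe_transects <- function(flock, config = attr(flock, "config"),
                              n_observers = 2L) {
  stopifnot(inherits(flock, "simulated_flock"))
  layout <- attr(flock, "layout")
  codes <- names(config$prevalence)
  with_op_seed(config$seed, "observe_transects", {
    rows <- list()
    for (obs in seq_len(n_observers)) {
      for (tr in layout$index) {
        in_tr <- flock$transect_index == tr
        n_in <- sum(in_tr)
        rec <- data.frame(house_id = config$geometry$house_id,
                          observer_id = obs, transect_index = tr,
                          stringsAsFactors = FALSE)
        for (code in codes) {
          a <- sum(flock[[code]][in_tr])
          u <- n_in - a
          rec[[code]] <- stats::rbinom(1L, a, config$sensitivity) +
            stats::rbinom(1L, u, config$fp_rate)
        }
        rows[[length(rows) + 1L]] <- rec
      }
    }
    do.call(rbind, rows)
  })
}

#' Sample birds from a simulated flock under a graded scheme
#'
#' Takes a simple random sample without replacement and converts each
#' bird's ground-truth state into an ordinal score: an affected bird
#' presents as major (score 2) with probability `severity_p2`, otherwise
#' minor (score 1); unaffected birds score 0.  Binary indicators (wounds
#' under the NorWel scheme) map affected to 1.
#'
#' @inheritParams observe_transects
#' @param scheme Scheme name, `"assurewel"` or `"norwel"` (controls which
#'   indicator columns are emitted and their level sets).
#' @return Data frame in the bird-score schema: `house_id`, `scheme`,
#'   `bird_ordinal`, `transect_index`, `transect_kind`, `vertical_level`,
#'   plus one score column per scheme indicator present in the simulation.
#' @export
sample_birds <- function(flock, config = attr(flock, "config"),
                         scheme = c("norwel", "assurewel")) {
  stopifnot(inherits(flock, "simulated_flock"))
  scheme <- match.arg(scheme)
  sch <- indicator_scheme(scheme)
  n <- config$sample_n
  if (n > nrow(flock)) stop("sample_n exceeds flock size", call. = FALSE)
  codes <- intersect(sch$indicators$code, names(config$prevalence))
  with_op_seed(config$seed, paste0("sample_birds_", scheme), {
    idx <- sample.int(nrow(flock), n)
    picked <- flock[idx, , drop = FALSE]
    out <- data.frame(house_id = config$geometry$house_id,
                      scheme = scheme,
                      bird_ordinal = seq_len(n),
                      transect_index = picked$transect_index,
                      transect_kind = picked$transect_kind,
                      vertical_level = picked$vertical_level,
                      stringsAsFactors = FALSE)
    for (code in codes) {
      lv <- scheme_levels(sch, code)
      aff <- picked[[code]]
      if (max(lv) == 2L) {
        sev <- stats::runif(n) < config$severity_p2
        out[[code]] <- ifelse(aff, ifelse(sev, 2L, 1L), 0L)
      } else {
        out[[code]] <- as.integer(aff)
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Power of a flock comparison under a sampling design
#'
#' Paired Monte-Carlo experiment: in each replicate two flocks are simulated
#' under `config_a` and `config_b` (identical apart from the stated
#' prevalences), observed with the chosen design, and a binomial logit model
#' with a flock factor is fitted; power is the fraction of replicates in
#' which the flock likelihood-ratio test rejects at `alpha`.
#'
#' * `method = "transect"` — whole-flock transect tallies (one observer,
#'   one cell per transect; trials = estimated birds per transect).
#' * `method = "sample_n"` — a fixed-size random bird sample per flock
#'   (one cell per flock; trials = `sample_n`; a bird counts as positive
#'   when its score is above 0).
#'
#' @param config_a,config_b [sim_config()]s for the two flocks; only the
#'   prevalences (and seed) may differ.
#' @param indicator Indicator code to compare.
#' @param method `"transect"` or `"sample_n"`.
#' @param replicates Number of Monte-Carlo replicates (at least 100).
#' @param alpha Test size (default 0.05).
#' @return List: `power`, `mc_se` (binomial Monte-Carlo standard error),
#'   `replicates`, `n_tested` (replicates with an estimable test), `alpha`,
#'   `method`.
#' @export
power_experiment <- function(config_a, config_b, indicator,
                             method = c("transect", "sample_n"),
                             replicates = 200L, alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(replicates >= 100L)
  pa <- config_a$prevalence[[indicator]]
  pb <- config_b$prevalence[[indicator]]
  if (pa == 0 && pb == 0) {
    stop("both prevalences are zero; power undefined", call. = FALSE)
  }
  base_seed <- op_seed(config_a$seed, paste0("power_", method, indicator))
  reject <- rep(NA, replicates)
  for (r in seq_len(replicates)) {
    seed_r <- (base_seed + r) %% 2147483647L
    ca <- config_a; ca$seed <- seed_r
    cb <- config_b; cb$seed <- (seed_r + 1000003L) %% 2147483647L
    fa <- simulate_flock(ca); fb <- simulate_flock(cb)
    if (method == "transect") {
      oa <- observe_transects(fa, ca, n_observers = 1L)
      ob <- observe_transects(fb, cb, n_observers = 1L)
      la <- attr(fa, "layout"); lb <- attr(fb, "layout")
      dat <- data.frame(
        flock = rep(c("A", "B"), c(nrow(oa), nrow(ob))),
        successes = c(oa[[indicator]], ob[[indicator]]),
        trials = c(la$estimated_birds[match(oa$transect_index, la$index)],
                   lb$estimated_birds[match(ob$transect_index, lb$index)]))
      # observation noise can push a tally past the apportioned population
      dat$successes <- pmin(dat$successes, dat$trials)
    } else {
      sa <- sample_birds(fa, ca, "norwel")
      sb <- sample_birds(fb, cb, "norwel")
      dat <- data.frame(
        flock = c("A", "B"),
        successes = c(sum(sa[[indicator]] > 0), sum(sb[[indicator]] > 0)),
        trials = c(nrow(sa), nrow(sb)))
    }
    res <- tryCatch({
      fit <- fit_binomial_glm(dat$successes, dat$trials, dat,
                              model_spec("flock"))
      factor_test(fit, "flock")
    }, no_variation = function(e) NULL,
       error = function(e) NULL)
    if (!is.null(res) && isTRUE(res$estimable)) {
      reject[r] <- res$p_value < alpha
    } else {
      reject[r] <- FALSE  # nothing to reject on: conservative non-rejection
    }
  }
  pow <- mean(reject)
  list(power = pow,
       mc_se = sqrt(pow * (1 - pow) / replicates),
       replicates = replicates, n_tested = sum(!is.na(reject)),
       alpha = alpha, method = method)
}
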