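#' Welfare indicator scoring schemes
#'
#' Three scoring schemes are supported:
#'
#' * `"aviary_transect"` — 12 binary whole-flock indicators tallied while
#'   walking transects: feather loss (FL) on head, back, breast and tail,
#'   wounds on head, back, tail and feet, dirty plumage, enlarged (pendulous)
#'   crop, sick, and dead.  A hen may be counted under more than one
#'   indicator, so counts are not disjoint.
#' * `"assurewel"` — 50 randomly sampled birds scored 0/1/2 for FL head,
#'   FL back and dirtiness, plus whole-flock descriptive items (beak
#'   trimming, antagonistic incidents, flightiness, birds needing further
#'   care, mortality).
#' * `"norwel"` — 50 randomly sampled birds scored 0/1/2 for FL on head,
#'   back, breast and tail and for dirtiness, and 0/1 for wounds on head,
#'   back and tail; the bird's location (transect and vertical level) is
#'   recorded.
#'
#' Indicator codes are fixed snake_case identifiers so CSV schemas stay
#' stable; the scheme carries the field definitions as metadata.
#'
#' @param scheme_name One of `"aviary_transect"`, `"assurewel"`, `"norwel"`.
#' @return An `indicator_scheme` object: a list with `scheme_name`,
#'   `indicators` (data frame: `code`, `body_site`, `levels`, `definition`),
#'   and for AssureWel a `flock_items` data frame of whole-flock fields.
#' @examples
#' indicator_scheme("aviary_transect")$indicators$code
#' @export
indicator_scheme <- function(scheme_name = c("aviary_transect", "assurewel",
                                             "norwel")) {
  scheme_name <- match.arg(scheme_name)
  ind <- switch(scheme_name,
    aviary_transect = data.frame(
      code = c("fl_head", "fl_back", "fl_breast", "fl_tail",
               "dirty", "wounds_head", "wounds_back", "wounds_tail",
               "wounds_feet", "enlarged_crop", "sick", "dead"),
      body_site = c("head", "back", "breast", "tail", "plumage",
                    "head", "back", "tail", "feet", "crop",
                    "whole bird", "whole bird"),
      levels = "0,1",
      definition = c(
        "missing feathers on the head incl. neck, >=5 cm diameter",
        "missing feathers on >=50% of the back incl. wings",
        "missing feathers on the breast, >=5 cm diameter",
        "missing or clearly damaged tail feathers, mainly shafts left",
        "prominent dark staining covering >=25% of the body",
        "prominent marks on head/neck from fresh or older wounds",
        "prominent marks on back incl. wings from wounds",
        "prominent marks on tail from wounds",
        "bumblefoot or prominent marks on the feet",
        "pendulous crop hanging in front of the breast",
        "clear signs of impaired health, often in a resting position",
        "dead bird found on the transect"),
      stringsAsFactors = FALSE),
    assurewel = data.frame(
      code = c("fl_head", "fl_back", "dirtiness"),
      body_site = c("head/neck", "back/vent", "plumage"),
      levels = "0,1,2",
      definition = c(
        "feather loss: 0 none, 1 < 5 cm, 2 > 5 cm diameter",
        "feather loss: 0 none, 1 < 5 cm, 2 > 5 cm diameter",
        "dirt: 0 clean, 1 soiling but no area > 5 cm, 2 soiling > 5 cm"),
      stringsAsFactors = FALSE),
    norwel = data.frame(
      code = c("fl_head", "fl_back", "fl_breast", "fl_tail",
               "dirty", "wounds_head", "wounds_back", "wounds_tail"),
      body_site = c("head", "back/wings", "breast", "tail", "plumage",
                    "head", "back/wings", "tail"),
      levels = c(rep("0,1,2", 5), rep("0,1", 3)),
      definition = c(
        "feather loss: 0 none, 1 < 5 cm, 2 > 5 cm diameter",
        "feather loss: 0 none, 1 < 5 cm, 2 > 5 cm diameter",
        "feather loss: 0 none, 1 < 5 cm, 2 > 5 cm diameter",
        "tail wear: 0 none, 1 some, 2 substantial (shafts left)",
        "dirt: 0 clean, 1 some, 2 > 50% of plumage",
        "wound on head: 0 absent, 1 clearly visible",
        "wound on back incl. wings: 0 absent, 1 clearly visible",
        "wound on tail: 0 absent, 1 clearly visible"),
      stringsAsFactors = FALSE))
  out <- list(scheme_name = scheme_name, indicators = ind)
  if (scheme_name == "assurewel") {
    out$flock_items <- data.frame(
      code = c("beak_trimmed", "antagonistic_incidents", "flightiness",
               "birds_needing_care", "mortality_previous", "mortality_to_date"),
      type = c("yes/no", "count", "calm|cautious|flighty", "count",
               "percent or unknown", "percent or unknown"),
      stringsAsFactors = FALSE)
  }
  class(out) <- "indicator_scheme"
  out
}

#' @export
print.indicator_scheme <- function(x, ...) {
  cat(sprintf("<indicator_scheme> %s: %d indicators\n",
              x$scheme_name, nrow(x$indicators)))
  print(x$indicators[, c("code", "levels")], row.names = FALSE)
  invisible(x)
}

scheme_levels <- function(scheme, code) {
  row <- scheme$indicators[scheme$indicators$code == code, , drop = FALSE]
  if (!nrow(row)) stop("unknown indicator code: ", code, call. = FALSE)
  as.integer(strsplit(row$levels, ",")[[1]])
}

#' Validate per-bird graded score records
#'
#' Checks a data frame of bird-level scores against a scheme: indicator
#' columns present, every score within the per-indicator level set, and
#' (for NorWel, where location is part of the protocol) `transect_index`
#' and `vertical_level` present and in range.
#'
#' @param records Data frame with columns `house_id`, `bird_ordinal`, one
#'   column per indicator code, and for NorWel `transect_index` and
#'   `vertical_level` (1--4: litter, 1st, 2nd, top tier).
#' @param scheme An [indicator_scheme()] (or its name).
#' @return Character vector of violations, empty when valid.
#' @export
validate_scores <- function(records, scheme) {
  if (is.character(scheme)) scheme <- indicator_scheme(scheme)
  v <- character(0)
  for (code in scheme$indicators$code) {
    if (!code %in% names(records)) {
      v <- c(v, sprintf("missing indicator column '%s'", code))
      next
    }
    lv <- scheme_levels(scheme, code)
    bad <- !(records[[code]] %in% lv)
    if (any(bad)) {
      v <- c(v, sprintf("indicator '%s': %d score(s) outside levels {%s}",
                        code, sum(bad), paste(lv, collapse = ",")))
    }
  }
  if (scheme$scheme_name == "norwel") {
    for (loc in c("transect_index", "vertical_level")) {
      if (!loc %in% names(records) || anyNA(records[[loc]])) {
        v <- c(v, sprintf("location column '%s' required for norwel", loc))
      }
    }
    if ("vertical_level" %in% names(records) &&
        !anyNA(records$vertical_level) &&
        any(!(records$vertical_level %in% 1:4))) {
      v <- c(v, "vertical_level must be in 1..4")
    }
  }
  v
}

#' Validate transect count records against a layout
#'
#' @param counts Data frame with `house_id`, `observer_id`, `transect_index`
#'   and one column per binary transect-scheme indicator, holding the number
#'   of birds tallied.
#' @param layout A layout from [estimate_birds_per_transect()].
#' @return Character vector of violations, empty when valid.
#' @export
validate_transect_counts <- function(counts, layout) {
  scheme <- indicator_scheme("aviary_transect")
  v <- character(0)
  for (code in scheme$indicators$code) {
    if (!code %in% names(counts)) {
      v <- c(v, sprintf("missing indicator column '%s'", code))
    } else if (any(!is.finite(counts[[code]]) | counts[[code]] < 0 |
                   counts[[code]] != round(counts[[code]]))) {
      v <- c(v, sprintf("indicator '%s': counts must be non-negative integers",
                        code))
    }
  }
  if (!all(counts$transect_index %in% layout$index)) {
    v <- c(v, "transect_index not present in layout")
  } else {
    est <- layout$estimated_birds[match(counts$transect_index, layout$index)]
    for (code in intersect(scheme$indicators$code, names(counts))) {
      over <- counts[[code]] > est
      if (any(over, na.rm = TRUE)) {
        v <- c(v, sprintf(
          "indicator '%s': count exceeds estimated birds in transect(s) %s",
          code, paste(counts$transect_index[which(over)], collapse = ",")))
      }
    }
  }
  v
}

#' Whole-flock prevalence from transect counts
#'
#' Converts tallied counts into prevalences: the frequency of birds showing
#' an indicator as a percentage of the estimated number of birds present in
#' that transect (flock size apportioned by transect width).
#'
#' @inheritParams validate_transect_counts
#' @return A `prevalence_estimate` data frame with one row per record row and
#'   indicator: `house_id`, `observer_id`, `transect_index`, `transect_kind`,
#'   `indicator`, `count`, `n_basis` (estimated birds), `p` (percent).
#' @export
transect_prevalence <- function(counts, layout) {
  v <- validate_transect_counts(counts, layout)
  if (length(v)) stop("invalid transect counts: ",
                      paste(v, collapse = "; "), call. = FALSE)
  codes <- indicator_scheme("aviary_transect")$indicators$code
  est <- layout$estimated_birds[match(counts$transect_index, layout$index)]
  kind <- layout$kind[match(counts$transect_index, layout$index)]
  out <- do.call(rbind, lapply(codes, function(code) {
    data.frame(house_id = counts$house_id,
               observer_id = counts$observer_id,
               transect_index = counts$transect_index,
               transect_kind = kind,
               indicator = code,
               count = as.integer(counts[[code]]),
               n_basis = est,
               p = 100 * counts[[code]] / est,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("prevalence_estimate", "data.frame")
  out
}

#' Sample prevalence with standard error for one graded score level
#'
#' For `n` sampled birds of which `k` carry exactly the given score level,
#' the prevalence is `p = 100 k / n` percent with standard error
#' `se = 100 * sqrt(phat (1 - phat) / (n - 1))`, `phat = k / n`.  The
#' `n - 1` denominator is the sample-variance form and is the one that
#' reproduces published 50-bird scheme tables to the printed decimal.
#'
#' @param records Data frame of bird-level scores (one row per bird) for a
#'   single house and scheme.
#' @param indicator Indicator code, e.g. `"fl_back"`.
#' @param score_level Score level whose prevalence is wanted (birds scoring
#'   exactly this level are counted).
#' @return One-row `prevalence_estimate` data frame: `indicator`,
#'   `score_level`, `k`, `n_basis`, `p`, `se` (all percentages).
#' @export
sample_prevalence <- function(records, indicator, score_level) {
  if (!indicator %in% names(records)) {
    stop("indicator column '", indicator, "' not found", call. = FALSE)
  }
  if (length(unique(records$house_id)) > 1L) {
    stop("records must come from a single house", call. = FALSE)
  }
  x <- records[[indicator]]
  n <- length(x)
  if (n < 2L) stop("need at least 2 scored birds (SE undefined)",
                   call. = FALSE)
  k <- sum(x == score_level)
  phat <- k / n
  out <- data.frame(indicator = indicator, score_level = score_level,
                    k = k, n_basis = n,
                    p = 100 * phat,
                    se = 100 * sqrt(phat * (1 - phat) / (n - 1)),
                    stringsAsFactors = FALSE)
  class(out) <- c("prevalence_estimate", "data.frame")
  out
}

#' Binomial standard error of a sample prevalence
#'
#' @param p Prevalence in percent.
#' @param n Number of birds sampled.
#' @return Standard error in percent, `100 * sqrt(p/100 * (1-p/100) / (n-1))`.
#' @export
prevalence_se <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 100), all(n >= 2))
  phat <- p / 100
  100 * sqrt(phat * (1 - phat) / (n - 1))
}

#' Aggregate prevalence estimates over a grouping factor
#'
#' Summarises subunit prevalences (e.g. one per observer-by-transect walk)
#' into per-group means with the standard error of the mean across subunits,
#' the layout used for flock, observer, transect-type and vertical-level
#' summary tables.  Groups with a single subunit get `se = 0` and are flagged
#' (`se_defined = FALSE`); empty groups are dropped with a warning.
#'
#' @param estimates A `prevalence_estimate` data frame (one row per subunit
#'   and indicator) with column `p` and the grouping column.
#' @param by Name of the grouping column, e.g. `"transect_kind"`.
#' @return Data frame: group, `indicator` (and `score_level` if present),
#'   `n_subunits`, `mean_p`, `se`, `se_defined`.
#' @export
aggregate_prevalence <- function(estimates, by) {
  if (!by %in% names(estimates)) {
    stop("grouping column '", by, "' not present", call. = FALSE)
  }
  keys <- c(by, "indicator",
            intersect("score_level", names(estimates)))
  drop_na <- is.na(estimates[[by]])
  if (any(drop_na)) {
    warning(sum(drop_na), " row(s) with missing '", by, "' dropped")
    estimates <- estimates[!drop_na, , drop = FALSE]
  }
  split_key <- interaction(estimates[keys], drop = TRUE, lex.order = TRUE)
  parts <- split(estimates, split_key)
  out <- do.call(rbind, lapply(parts, function(d) {
    m <- mean(d$p)
    n <- nrow(d)
    se <- if (n >= 2) stats::sd(d$p) / sqrt(n) else 0
    cbind(d[1L, keys, drop = FALSE],
          data.frame(n_subunits = n, mean_p = m, se = se,
                     se_defined = n >= 2))
  }))
  rownames(out) <- NULL
  out
}

flightiness_levels <- c("calm", "cautious", "flighty")

#' Descriptive whole-flock summary (AssureWel flock-level items)
#'
#' Echoes the whole-flock descriptive fields with type checking and no
#' statistics: beak trimming, number of antagonistic incidents, flightiness
#' category, birds needing further care, and producer-reported mortality.
#' `"unknown"` is a legal value for mortality fields and is preserved as
#' text, never coerced to a number.
#'
#' @param house_id Flock/house identifier.
#' @param beak_trimmed `"yes"`, `"no"` or `NA`.
#' @param antagonistic_incidents Non-negative count of observed incidents.
#' @param flightiness One of `"calm"`, `"cautious"`, `"flighty"`.
#' @param birds_needing_care Non-negative count.
#' @param mortality_previous,mortality_to_date Percent as number, or the
#'   string `"unknown"`.
#' @return One-row data frame with the checked values (mortality columns are
#'   character to allow `"unknown"`).
#' @export
descriptive_flock_summary <- function(house_id,
                                      beak_trimmed = NA,
                                      antagonistic_incidents = NA_integer_,
                                      flightiness = NA_character_,
                                      birds_needing_care = NA_integer_,
                                      mortality_previous = "unknown",
                                      mortality_to_date = "unknown") {
  if (!is.na(flightiness) &&
      !tolower(flightiness) %in% flightiness_levels) {
    stop("flightiness must be one of ",
         paste(flightiness_levels, collapse = ", "), call. = FALSE)
  }
  if (!is.na(beak_trimmed) &&
      !tolower(as.character(beak_trimmed)) %in% c("yes", "no")) {
    stop("beak_trimmed must be 'yes' or 'no'", call. = FALSE)
  }
  chk_count <- function(x, nm) {
    if (!is.na(x) && (!is.numeric(x) || x < 0 || x != round(x))) {
      stop(nm, " must be a non-negative count", call. = FALSE)
    }
    as.integer(x)
  }
  chk_mort <- function(x, nm) {
    x <- as.character(x)
    if (!is.na(x) && tolower(x) != "unknown" &&
        is.na(suppressWarnings(as.numeric(x)))) {
      stop(nm, " must be a percentage or 'unknown'", call. = FALSE)
    }
    if (!is.na(x) && tolower(x) == "unknown") "unknown" else x
  }
  data.frame(
    house_id = as.character(house_id),
    beak_trimmed = if (is.na(beak_trimmed)) NA_character_
                   else tolower(as.character(beak_trimmed)),
    antagonistic_incidents = chk_count(antagonistic_incidents,
                                       "antagonistic_incidents"),
    flightiness = if (is.na(flightiness)) NA_character_
                  else tolower(flightiness),
    birds_needing_care = chk_count(birds_needing_care, "birds_needing_care"),
    mortality_previous = chk_mort(mortality_previous, "mortality_previous"),
    mortality_to_date = chk_mort(mortality_to_date, "mortality_to_date"),
    stringsAsFactors = FALSE)
}
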