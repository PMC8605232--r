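#' House geometry for a loose-housed aviary flock
#'
#' Describes the physical layout of one hen house as seen from above: the
#' overall house width, the widths of the littered aisles between (and beside)
#' the rows of tiered aviary structures, the number of structure rows, the
#' flock size, and the regulatory usable area.  Each aisle defines one walking
#' transect; a house with `n` structure rows has `n + 1` aisles and therefore
#' `n + 1` transects (2 to 4 in practice).
#'
#' The constructor performs type checks only and never errors on inconsistent
#' measurements; use [validate_geometry()] for the invariant report.  All
#' downstream operations require a geometry that validates cleanly.
#'
#' @param house_id Identifier for the house/flock (character or integer).
#' @param house_width Total inner width of the house in meters.
#' @param aisle_widths Numeric vector of aisle widths in meters, ordered from
#'   the left wall (relative to the entrance door) to the right wall.
#' @param n_structures Number of tiered-structure rows.
#' @param flock_size Number of hens housed.
#' @param usable_area Usable area in square meters (area at least 30 cm wide,
#'   slope at most 14 percent, headroom at least 45 cm, excluding nests).
#' @param floor_area Littered floor area in square meters (optional).
#' @param n_vertical_levels Number of vertical levels birds occupy; default 4
#'   (litter plus 3 tiers).
#'
#' @return An object of class `house_geometry`.
#' @seealso [validate_geometry()], [transect_widths()],
#'   [estimate_birds_per_transect()], [animal_density()]
#' @examples
#' g <- house_geometry("flock4", house_width = 10,
#'                     aisle_widths = c(2.11, 2.11), n_structures = 1,
#'                     flock_size = 7200, usable_area = 815)
#' validate_geometry(g)
#' estimate_birds_per_transect(g)
#' @export
house_geometry <- function(house_id, house_width, aisle_widths, n_structures,
                           flock_size, usable_area, floor_area = NA_real_,
                           n_vertical_levels = 4L) {
  stopifnot(length(house_id) == 1L,
            is.numeric(house_width), length(house_width) == 1L,
            is.numeric(aisle_widths),
            is.numeric(n_structures), length(n_structures) == 1L,
            is.numeric(flock_size), length(flock_size) == 1L,
            is.numeric(usable_area), length(usable_area) == 1L)
  structure(
    list(house_id = as.character(house_id),
         house_width = as.numeric(house_width),
         aisle_widths = as.numeric(aisle_widths),
         n_structures = as.integer(n_structures),
         flock_size = as.integer(round(flock_size)),
         usable_area = as.numeric(usable_area),
         floor_area = as.numeric(floor_area),
         n_vertical_levels = as.integer(n_vertical_levels)),
    class = "house_geometry")
}

#' @export
print.house_geometry <- function(x, ...) {
  cat(sprintf("<house_geometry> %s\n", x$house_id))
  cat(sprintf("  house width : %.2f m, %d structure row(s), %d aisle(s)\n",
              x$house_width, x$n_structures, length(x$aisle_widths)))
  cat(sprintf("  aisles      : %s m\n",
              paste(format(x$aisle_widths), collapse = ", ")))
  cat(sprintf("  flock       : %d hens, usable area %.0f m2\n",
              x$flock_size, x$usable_area))
  invisible(x)
}

#' Report violated geometry invariants
#'
#' Checks a [house_geometry()] object against the layout invariants (aisle
#' count equals structure rows plus one, positive widths, aisles narrower than
#' the house, positive flock size and usable area) and returns every violation
#' found.  Never raises: an invalid object yields a non-empty report.
#'
#' @param geometry A `house_geometry` object.
#' @return Character vector of human-readable violations, empty when the
#'   geometry is consistent.  Class `geometry_validation`.
#' @export
validate_geometry <- function(geometry) {
  v <- character(0)
  g <- geometry
  if (!inherits(g, "house_geometry")) {
    return(structure("not a house_geometry object",
                     class = c("geometry_validation", "character")))
  }
  if (length(g$aisle_widths) != g$n_structures + 1L) {
    v <- c(v, sprintf(
      "aisle count (%d) must equal n_structures + 1 (%d)",
      length(g$aisle_widths), g$n_structures + 1L))
  }
  if (any(!is.finite(g$aisle_widths)) || any(g$aisle_widths <= 0)) {
    v <- c(v, "every aisle width must be a positive finite number")
  }
  if (!is.finite(g$house_width) || g$house_width <= 0) {
    v <- c(v, "house_width must be positive")
  }
  if (all(is.finite(g$aisle_widths)) &&
      sum(g$aisle_widths) >= g$house_width) {
    v <- c(v, sprintf(
      "sum of aisle widths (%.2f m) must be less than house width (%.2f m)",
      sum(g$aisle_widths), g$house_width))
  }
  if (g$n_structures < 1L) {
    v <- c(v, "n_structures must be at least 1")
  }
  if (!is.finite(g$flock_size) || g$flock_size <= 0) {
    v <- c(v, "flock_size must be positive")
  }
  if (!is.finite(g$usable_area) || g$usable_area <= 0) {
    v <- c(v, "usable_area must be positive")
  }
  if (g$n_vertical_levels < 1L) {
    v <- c(v, "n_vertical_levels must be at least 1")
  }
  structure(v, class = c("geometry_validation", "character"))
}

assert_valid_geometry <- function(geometry) {
  v <- validate_geometry(geometry)
  if (length(v)) {
    stop("invalid house geometry [", geometry$house_id, "]: ",
         paste(v, collapse = "; "), call. = FALSE)
  }
  invisible(geometry)
}

#' Derive the width of one tiered-structure row
#'
#' The structure width is not measured directly; it is recovered from the
#' house width and the measured aisle widths as
#' `(house_width - sum(aisle_widths)) / n_structures`.  Working from the
#' derived (unrounded) value rather than a pre-rounded one is what makes the
#' transect bird apportionment reproduce whole-house tallies exactly.
#'
#' @inheritParams validate_geometry
#' @return Structure-row width in meters (strictly positive).
#' @export
derive_structure_width <- function(geometry) {
  assert_valid_geometry(geometry)
  w <- (geometry$house_width - sum(geometry$aisle_widths)) /
    geometry$n_structures
  if (!is.finite(w) || w <= 0) {
    stop(sprintf(
      paste0("geometry inconsistency [%s]: house_width %.2f minus aisles ",
             "%.2f leaves non-positive structure width over %d structure(s)"),
      geometry$house_id, geometry$house_width, sum(geometry$aisle_widths),
      geometry$n_structures), call. = FALSE)
  }
  w
}

#' Transect widths for a house
#'
#' Each transect comprises the littered aisle plus half the width of the
#' space under each adjacent aviary structure: wall transects (first and
#' last) absorb one half-structure, central transects absorb two.  The
#' widths therefore partition the house width exactly.
#'
#' @inheritParams validate_geometry
#' @return A `transect_layout` data frame with columns `index` (1 = left
#'   wall relative to the entrance door), `kind` (`"wall"` or `"central"`),
#'   and `width` (meters).
#' @export
transect_widths <- function(geometry) {
  sw <- derive_structure_width(geometry)
  n <- length(geometry$aisle_widths)
  kind <- rep("central", n)
  kind[c(1L, n)] <- "wall"
  half <- ifelse(kind == "wall", sw / 2, sw)
  layout <- data.frame(index = seq_len(n), kind = kind,
                       width = geometry$aisle_widths + half,
                       stringsAsFactors = FALSE)
  stopifnot(abs(sum(layout$width) - geometry$house_width) < 1e-9)
  class(layout) <- c("transect_layout", "data.frame")
  attr(layout, "house_id") <- geometry$house_id
  layout
}

# round half away from zero (base round() is half-to-even, which would turn
# the 1562.5-bird wall transect into 1562, not the tallied 1563)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Apportion the flock to transects
#'
#' Under the homogeneity assumption the expected number of birds present in a
#' transect is proportional to its width: the flock size is split as
#' `flock_size * width / house_width`, rounded half away from zero.  These
#' per-transect populations are the denominators for whole-flock prevalence
#' estimation.
#'
#' @inheritParams validate_geometry
#' @return The [transect_widths()] layout with an added integer column
#'   `estimated_birds`.
#' @export
estimate_birds_per_transect <- function(geometry) {
  layout <- transect_widths(geometry)
  layout$estimated_birds <- as.integer(round_half_up(
    geometry$flock_size * layout$width / geometry$house_width))
  stopifnot(all(layout$estimated_birds > 0L))
  layout
}

#' Animal density on usable area
#'
#' Stocking density as birds per square meter of usable area, truncated (not
#' rounded) to two decimals.
#'
#' @param flock_size Number of birds (positive).
#' @param usable_area Usable area in square meters (positive).
#' @return Density in birds per square meter, truncated to 2 decimals.
#' @export
animal_density <- function(flock_size, usable_area) {
  if (!is.numeric(flock_size) || !is.numeric(usable_area) ||
      !is.finite(flock_size) || !is.finite(usable_area) ||
      flock_size <= 0 || usable_area <= 0) {
    stop("flock_size and usable_area must be positive numbers", call. = FALSE)
  }
  # tiny epsilon guards exact quotients against binary representation error
  trunc(100 * flock_size / usable_area + 1e-9) / 100
}
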