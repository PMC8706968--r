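#' Poisson MOI from the positive-cell fraction
#'
#' Under the Poisson infection model the fraction of uninfected cells is
#' `P(0) = exp(-MOI)`, so `MOI = -ln(1 - P(1))` where `P(1)` is the
#' fluorescence-positive fraction measured by FACS.
#'
#' @param p1 Positive fraction(s) in `[0, 1)`.
#' @return MOI value(s) (pfu per cell).
#' @examples
#' moi_from_fraction(0.39) # ~0.5
#' @export
moi_from_fraction <- function(p1) {
  if (any(p1 < 0 | p1 >= 1)) {
    stop("positive fraction must lie in [0, 1)", call. = FALSE)
  }
  -log(1 - p1)
}

#' Positive-cell fraction from the Poisson MOI
#'
#' Inverse of [moi_from_fraction()]: `P(1) = 1 - exp(-MOI)`. At the MOIs
#' used for single-copy library integration (0.5-0.7) the expected FACS
#' window is 39-50% positive cells.
#'
#' @param moi MOI value(s), non-negative.
#' @return Positive fraction(s).
#' @examples
#' round(100 * fraction_from_moi(c(0.5, 0.7))) # 39 and 50 percent
#' @export
fraction_from_moi <- function(moi) {
  if (any(moi < 0)) stop("MOI must be non-negative", call. = FALSE)
  1 - exp(-moi)
}

#' Plan the lentivirus volume for a target MOI
#'
#' Converts each titration point to the MOI scale (where virus dose is
#' additive, unlike the saturating positive fraction), fits the standard
#' curve MOI = k * volume through the origin by least squares, and returns
#' the volume delivering `target_moi`, scaled to the assay cell count
#' relative to the titration cell count (dose per cell is the conserved
#' quantity).
#'
#' @param points Tibble/data.frame with `volume` (uL) and `positive_fraction`
#'   in `[0, 1)`; at least two distinct volumes.
#' @param target_moi Desired MOI, e.g. 0.5-0.7 for library transduction.
#' @param cells Cell count of the planned assay.
#' @param titration_cells Cell count used in the titration wells.
#' @return List: `volume_ul` (recommendation), `k` (MOI per uL per
#'   titration-well cells), `curve` (tibble of fitted points).
#' @export
plan_infection <- function(points, target_moi, cells = 4e6,
                           titration_cells = 2e5) {
  stopifnot(target_moi > 0, cells > 0, titration_cells > 0)
  pts <- tibble::as_tibble(points)
  pts <- pts[pts$volume > 0, , drop = FALSE]
  if (length(unique(pts$volume)) < 2) {
    stop("need at least two titration points with distinct non-zero volumes",
         call. = FALSE)
  }
  if (all(pts$positive_fraction == 0)) {
    stop("all positive fractions are zero: no signal to fit", call. = FALSE)
  }
  pts$moi <- moi_from_fraction(pts$positive_fraction)
  fit <- stats::lm(moi ~ 0 + volume, data = pts)
  k <- unname(stats::coef(fit)[["volume"]])
  if (k <= 0) stop("fitted titration slope is not positive", call. = FALSE)
  volume <- target_moi / k * (cells / titration_cells)
  list(volume_ul = volume, k = k,
       curve = tibble::tibble(volume = pts$volume, moi = pts$moi,
                              fitted_moi = k * pts$volume))
}
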