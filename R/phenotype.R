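#' Percentage growth inhibition
#'
#' `100 - (x/y * 100)`, where `x` is the growth (OD600) observed in the
#' treatment atmosphere and `y` the growth in the matched control
#' atmosphere. Negative values mean growth stimulation and are reported
#' as-is, never clipped.
#'
#' @param x treatment growth, OD600 (>= 0); vectorised.
#' @param y control growth, OD600 (> 0); vectorised.
#' @return percentage inhibition (may be negative).
#' @export
percent_inhibition <- function(x, y) {
  stopifnot(length(x) == length(y) || length(x) == 1L || length(y) == 1L)
  if (any(y <= 0)) stop("control growth 'y' must be positive")
  if (any(x < 0)) stop("treatment growth 'x' must be non-negative")
  100 - (x / y * 100)
}

#' Siderophore halo statistic
#'
#' The difference between the diameter of colony plus halo and the diameter
#' of the colony alone on a Chrome Azurol S plate — the plotted measure of
#' siderophore excretion.
#'
#' @param halo_diameter diameter of colony plus halo (mm); vectorised.
#' @param colony_diameter diameter of colony alone (mm).
#' @return halo width in mm (>= 0).
#' @export
halo_statistic <- function(halo_diameter, colony_diameter) {
  if (any(colony_diameter < 0)) stop("diameters must be non-negative")
  if (any(halo_diameter < colony_diameter))
    stop("halo diameter smaller than colony diameter: measurement inconsistency")
  halo_diameter - colony_diameter
}

#' Phosphorylated-regulator fraction
#'
#' The phosphorylated form expressed as a percentage of the total
#' (phosphorylated + unphosphorylated) band intensity, e.g. ArcA-P as a
#' percentage of total ArcA.
#'
#' @param intensity_phosphorylated,intensity_unphosphorylated non-negative
#'   band intensities, not both zero; vectorised.
#' @return percentage in `[0, 100]`.
#' @export
arcap_fraction <- function(intensity_phosphorylated, intensity_unphosphorylated) {
  p <- intensity_phosphorylated; u <- intensity_unphosphorylated
  if (any(p < 0) || any(u < 0)) stop("intensities must be non-negative")
  if (any(p + u == 0)) stop("both intensities zero: fraction undefined")
  100 * p / (p + u)
}
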