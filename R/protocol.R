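#' Relative-position protocol of an in situ experiment
#'
#' Describes the ordered SO/LG+PL relative positions at which isometric
#' forces are recorded. In calibration mode both LG+PL tendons are
#' repositioned together (muscle lengths constant); in testing mode only the
#' proximal LG+PL tendon is repositioned. The default protocol spans -3 to
#' +3 mm in 1-mm steps around the reference position (0 mm, corresponding to
#' 90 degree knee and ankle angles).
#'
#' @param positions_mm Strictly increasing relative positions (mm),
#'   containing exactly one zero (the reference position).
#' @param mode `"calibration"` (both tendons repositioned) or `"testing"`
#'   (proximal tendon only).
#' @return An object of class `position_protocol` with elements
#'   `positions_mm`, `reference_index` and `mode`.
#' @export
position_protocol <- function(positions_mm = -3:3,
                              mode = c("calibration", "testing")) {
  mode <- match.arg(mode)
  if (!is.numeric(positions_mm) || !all(is.finite(positions_mm))) {
    stop("`positions_mm` must be finite numeric", call. = FALSE)
  }
  if (any(diff(positions_mm) <= 0)) {
    stop("`positions_mm` must be strictly increasing", call. = FALSE)
  }
  ref <- which(positions_mm == 0)
  if (length(ref) != 1L) {
    stop("`positions_mm` must contain exactly one reference position (0 mm)",
         call. = FALSE)
  }
  structure(list(positions_mm = as.numeric(positions_mm),
                 reference_index = ref,
                 mode = mode),
            class = "position_protocol")
}

#' @export
print.position_protocol <- function(x, ...) {
  cat("Position protocol (", x$mode, "): ",
      paste(x$positions_mm, collapse = ", "), " mm; reference at index ",
      x$reference_index, "\n", sep = "")
  invisible(x)
}

#' Map LG+PL proximal displacement to knee joint angle
#'
#' Affine map between the imposed proximal LG+PL displacement and the knee
#' angle producing an equivalent muscle-tendon length change in vivo. Only
#' the anchor point is fixed by the preparation: zero displacement
#' corresponds to the 90 degree knee (and ankle) reference configuration.
#' The slope depends on the moment arm and is configurable; the default of
#' 10 deg/mm places the calibrated +/-3 mm span over a 60-120 degree knee
#' range.
#'
#' @param position_mm Proximal LG+PL displacement(s), mm.
#' @param slope_deg_mm Slope of the map, degrees per mm. Default 10.
#' @param intercept_deg Knee angle at zero displacement, degrees. Default 90.
#' @return Knee angle(s) in degrees.
#' @export
position_to_knee_angle <- function(position_mm, slope_deg_mm = 10,
                                   intercept_deg = 90) {
  if (!is.numeric(position_mm) || !all(is.finite(position_mm))) {
    stop("`position_mm` must be finite numeric", call. = FALSE)
  }
  stopifnot(is.numeric(slope_deg_mm), is.numeric(intercept_deg),
            is.finite(slope_deg_mm), is.finite(intercept_deg))
  intercept_deg + slope_deg_mm * position_mm
}
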