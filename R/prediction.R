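#' Predict the LG+PL force difference under proximal-only repositioning
#'
#' Forward prediction for the testing protocol, in which only the proximal
#' LG+PL tendon is repositioned: over each displacement segment the INT
#' stiffness is scaled by the per-segment factor \eqn{r_j} (the ratio of
#' myofascially transmitted force under proximal-only vs full loading),
#' while NV1 and NV2 contribute with their calibrated stiffness:
#' \deqn{\Delta F^{mod}_{LGPL}(\Delta P) = \Delta F^{mod}(P_{REF}) +
#'   \sum_j (r_j \hat K_{INT,j} + \hat K_{NV1,j} + \hat K_{NV2,j}) w_j}
#' with signed stiffness, segment widths \eqn{w_j} covered by \eqn{\Delta P},
#' and odd symmetry for negative displacements. With all \eqn{r_j = 1} this
#' reduces exactly to the calibration forward model [forward_delta_f()].
#'
#' @param set A [stiffness_set()].
#' @param r Per-segment INT scale factors (length = segment count).
#' @param dp_mm Grid of proximal displacements (mm) within the covered span.
#' @param offset_N Predicted force difference at the reference position
#'   (default 0; set to a measured reference value when validating against
#'   experimental data).
#' @return A data frame of class `prediction_result` with columns
#'   `dp_prox_mm` and `delta_f_mod_N`; attributes `r`, `offset_N` and
#'   `stiffness`.
#' @export
#' @examples
#' predict_delta_f(bundled_stiffness("NO"), r = c(0.07, 0.13, 0.21),
#'                 dp_mm = -3:3)
predict_delta_f <- function(set, r, dp_mm, offset_N = 0) {
  stopifnot(inherits(set, "stiffness_set"))
  if (!is.numeric(offset_N) || length(offset_N) != 1L || !is.finite(offset_N)) {
    stop("`offset_N` must be a single finite force", call. = FALSE)
  }
  fwd <- forward_delta_f(set, dp_mm, r = r)
  structure(data.frame(dp_prox_mm = dp_mm,
                       delta_f_mod_N = offset_N + fwd$delta_f_lgpl_N),
            r = r, offset_N = offset_N, stiffness = set,
            class = c("prediction_result", "data.frame"))
}

#' Bland-Altman agreement between measured and predicted forces
#'
#' Bias is the mean difference (measured minus predicted); the limits of
#' agreement are bias +/- 1.96 times the sample (n-1) standard deviation of
#' the differences.
#'
#' @param measured,predicted Aligned force series (N), length >= 2.
#' @return An object of class `agreement_stats`: list with `bias_N`,
#'   `loa_lower_N`, `loa_upper_N`, `sd_diff_N`, `n`.
#' @export
bland_altman <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    stop("`measured` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(measured) < 2L) {
    stop("at least 2 paired values are needed for limits of agreement",
         call. = FALSE)
  }
  if (!all(is.finite(measured)) || !all(is.finite(predicted))) {
    stop("inputs must be finite", call. = FALSE)
  }
  d <- measured - predicted
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias_N = bias,
                 loa_lower_N = bias - 1.96 * s,
                 loa_upper_N = bias + 1.96 * s,
                 sd_diff_N = s,
                 n = length(d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n",
      "  bias: ", format(x$bias_N), " N\n",
      "  limits of agreement: [", format(x$loa_lower_N), ", ",
      format(x$loa_upper_N), "] N\n", sep = "")
  invisible(x)
}

#' Express values as a percentage of their total range
#'
#' Helper for Bland-Altman plots across animals with different force ranges:
#' maps a series onto \eqn{(x - \min x) / (\max x - \min x) \cdot 100}.
#'
#' @param x Numeric vector with non-zero range.
#' @return Numeric vector in \[0, 100\].
#' @export
percent_of_range <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) {
    stop("`x` has zero range; percentage of range undefined", call. = FALSE)
  }
  (x - rng[1L]) / diff(rng) * 100
}

#' Linear regression of SO force change on the LG+PL force difference
#'
#' Ordinary least squares fit of \eqn{\Delta F_{SO}} on
#' \eqn{\Delta F_{LGPL}}. A strong positive relation indicates that the
#' force discrepancy at the LG+PL tendons is balanced by force exerted at
#' the SO distal tendon, i.e. transmitted between the muscles through their
#' connective tissue interface.
#'
#' @param d_so \eqn{\Delta F_{SO}} series (N).
#' @param d_lgpl \eqn{\Delta F_{LGPL}} series (N); the predictor, must have
#'   non-zero variance.
#' @return List with `slope`, `intercept`, `r` (correlation coefficient)
#'   and `n`.
#' @export
regress_so_vs_lgpl <- function(d_so, d_lgpl) {
  if (length(d_so) != length(d_lgpl) || length(d_so) < 3L) {
    stop("need >= 3 aligned pairs", call. = FALSE)
  }
  if (stats::var(d_lgpl) == 0) {
    stop("predictor has zero variance; the fit is degenerate", call. = FALSE)
  }
  fit <- stats::lm(d_so ~ d_lgpl)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(d_so, d_lgpl),
       n = length(d_so))
}
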