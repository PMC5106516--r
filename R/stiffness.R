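#' Piecewise-linear stiffness of one epimuscular pathway
#'
#' Collagenous epimuscular linkages recruit fibres progressively with
#' extension, which is represented here as a piecewise-linear force-extension
#' relation: one signed stiffness value per displacement-magnitude band.
#' The default bands are \[0,1\], \[1,2\] and \[2,3\] mm of SO/LG+PL relative
#' displacement, matching the 1-mm steps of the calibration protocol.
#'
#' @param pathway Pathway label, one of `"INT"` (intermuscular connective
#'   tissue), `"NV1"` (SO neurovascular tract) or `"NV2"` (proximal LG+PL
#'   neurovascular tract).
#' @param k_mN_mm Numeric vector of signed segment stiffness values, in
#'   mN/mm; one per segment (length `length(breakpoints_mm) - 1`). The sign
#'   encodes the direction of the transmitted force relative to the
#'   proximal-distal LG+PL force difference.
#' @param breakpoints_mm Strictly increasing segment breakpoints in mm,
#'   starting at 0. Default `0:3`.
#' @param group Connectivity group label, `"NO"` (normal) or `"TI"`
#'   (tissue-integrating mesh, enhanced connectivity), or `NA`.
#' @param symmetric Logical; if `TRUE` (default) the force-extension relation
#'   is extended to negative displacements by odd symmetry,
#'   F(-P) = -F(P). If `FALSE`, negative displacements are outside the
#'   covered span.
#'
#' @return An object of class `piecewise_stiffness`.
#' @seealso [stiffness_set()], [pathway_force()], [fit_piecewise_stiffness()]
#' @export
#' @examples
#' piecewise_stiffness("INT", c(239.8, 171.7, 143.9), group = "NO")
piecewise_stiffness <- function(pathway, k_mN_mm, breakpoints_mm = 0:3,
                                group = NA_character_, symmetric = TRUE) {
  pathway <- match.arg(pathway, c("INT", "NV1", "NV2"))
  if (!is.numeric(k_mN_mm) || !all(is.finite(k_mN_mm))) {
    stop("`k_mN_mm` must be finite numeric stiffness values", call. = FALSE)
  }
  if (!is.numeric(breakpoints_mm) || length(breakpoints_mm) < 2L ||
      any(diff(breakpoints_mm) <= 0)) {
    stop("`breakpoints_mm` must be strictly increasing with >= 2 values",
         call. = FALSE)
  }
  if (abs(breakpoints_mm[1L]) > .Machine$double.eps) {
    stop("`breakpoints_mm` must start at 0 (the reference position)",
         call. = FALSE)
  }
  if (length(k_mN_mm) != length(breakpoints_mm) - 1L) {
    stop("need one stiffness value per segment: length(k_mN_mm) must equal ",
         "length(breakpoints_mm) - 1", call. = FALSE)
  }
  if (!is.na(group)) group <- match.arg(group, c("NO", "TI"))
  structure(
    list(pathway = pathway,
         k_mN_mm = as.numeric(k_mN_mm),
         breakpoints_mm = as.numeric(breakpoints_mm),
         group = group,
         symmetric = isTRUE(symmetric)),
    class = "piecewise_stiffness"
  )
}

#' @export
print.piecewise_stiffness <- function(x, ...) {
  cat("Piecewise-linear pathway stiffness: ", x$pathway,
      if (!is.na(x$group)) paste0(" (group ", x$group, ")"), "\n", sep = "")
  seg <- paste0("[", x$breakpoints_mm[-length(x$breakpoints_mm)], ",",
                x$breakpoints_mm[-1L], "] mm")
  print(stats::setNames(x$k_mN_mm, seg))
  cat(if (x$symmetric) "odd-symmetric for negative displacements\n"
      else "positive displacements only\n")
  invisible(x)
}

#' Bundle the three epimuscular pathway stiffnesses of one group
#'
#' A `stiffness_set` holds exactly the three modelled pathways (INT, NV1,
#' NV2) for one connectivity group, together with the dimensionless
#' neurovascular length-ratio parameter `c` used by the three-condition
#' estimator (ratio of NV1 length before vs after resection of the
#' myofascial linkages; default 0.9).
#'
#' @param int,nv1,nv2 [piecewise_stiffness()] objects with matching
#'   breakpoints, for pathways INT, NV1 and NV2 respectively.
#' @param group Group label `"NO"` or `"TI"`.
#' @param c Dimensionless NV1 length-ratio parameter, in (0, 1]. Default 0.9.
#'
#' @return An object of class `stiffness_set` with elements `pathways`
#'   (named list of `piecewise_stiffness`), `group` and `c`.
#' @export
#' @examples
#' ss <- stiffness_set(
#'   piecewise_stiffness("INT", c(239.8, 171.7, 143.9)),
#'   piecewise_stiffness("NV1", c(21.7, 0.4, 34.6)),
#'   piecewise_stiffness("NV2", c(-56.6, -30.8, -17.1)),
#'   group = "NO")
#' forward_delta_f(ss, -3:3)
stiffness_set <- function(int, nv1, nv2, group = NA_character_, c = 0.9) {
  paths <- list(INT = int, NV1 = nv1, NV2 = nv2)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!inherits(p, "piecewise_stiffness")) {
      stop("`", tolower(nm), "` must be a piecewise_stiffness object",
           call. = FALSE)
    }
    if (p$pathway != nm) {
      stop("pathway label mismatch: expected ", nm, ", got ", p$pathway,
           call. = FALSE)
    }
  }
  bp <- paths$INT$breakpoints_mm
  if (!identical(bp, paths$NV1$breakpoints_mm) ||
      !identical(bp, paths$NV2$breakpoints_mm)) {
    stop("all three pathways must share the same breakpoints", call. = FALSE)
  }
  check_c(c)
  if (!is.na(group)) group <- match.arg(group, c("NO", "TI"))
  structure(list(pathways = paths, group = group, c = as.numeric(c)),
            class = "stiffness_set")
}

check_c <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0 || c > 1) {
    stop("`c` must be a single value in (0, 1]", call. = FALSE)
  }
  invisible(c)
}

#' @export
print.stiffness_set <- function(x, ...) {
  cat("Epimuscular stiffness set",
      if (!is.na(x$group)) paste0(" (group ", x$group, ")"),
      ", c = ", format(x$c), "\n", sep = "")
  k <- t(vapply(x$pathways, `[[`, numeric(length(x$pathways$INT$k_mN_mm)),
                "k_mN_mm"))
  colnames(k) <- paste0("K", seq_len(ncol(k)), " (mN/mm)")
  print(k)
  invisible(x)
}

#' Segment stiffness values of a stiffness set as a matrix
#'
#' @param set A [stiffness_set()].
#' @return Numeric matrix, rows INT/NV1/NV2, one column per segment, mN/mm.
#' @export
segment_stiffness <- function(set) {
  stopifnot(inherits(set, "stiffness_set"))
  nseg <- length(set$pathways$INT$k_mN_mm)
  k <- t(vapply(set$pathways, `[[`, numeric(nseg), "k_mN_mm"))
  colnames(k) <- paste0("K", seq_len(nseg))
  k
}

#' Cumulative force carried by one pathway at given relative positions
#'
#' Integrates the signed segment stiffness from the reference position (0 mm)
#' to each requested relative position. Negative positions use odd symmetry
#' when the pathway is marked symmetric, and are an error otherwise.
#' Positions beyond the last breakpoint raise an extrapolation error: the
#' model is never evaluated outside the calibrated span.
#'
#' @param ps A [piecewise_stiffness()].
#' @param position_mm Numeric vector of relative positions (mm).
#' @return Numeric vector of forces in N (note: stiffness is in mN/mm).
#' @export
pathway_force <- function(ps, position_mm) {
  stopifnot(inherits(ps, "piecewise_stiffness"))
  if (!is.numeric(position_mm) || !all(is.finite(position_mm))) {
    stop("`position_mm` must be finite numeric", call. = FALSE)
  }
  bp <- ps$breakpoints_mm
  span <- bp[length(bp)]
  tol <- 1e-12
  if (any(abs(position_mm) > span + tol)) {
    stop("position ", format(position_mm[which.max(abs(position_mm))]),
         " mm lies outside the covered span [", -span, ", ", span,
         "] mm; extrapolation is not supported", call. = FALSE)
  }
  if (!ps$symmetric && any(position_mm < -tol)) {
    stop("negative positions requested but the pathway is not marked ",
         "symmetric", call. = FALSE)
  }
  ap <- abs(position_mm)
  lo <- bp[-length(bp)]
  hi <- bp[-1L]
  # overlap of [0, |P|] with each segment, times the segment stiffness
  widths <- pmin(rep(ap, each = length(lo)), hi) - lo
  widths <- matrix(pmax(widths, 0), nrow = length(lo))
  f_mN <- as.numeric(crossprod(widths, ps$k_mN_mm))
  sign(position_mm) * f_mN / 1000
}

#' Forward lumped model: net LG+PL tendon force difference vs position
#'
#' Evaluates the calibrated forward model at the given SO/LG+PL relative
#' positions: each pathway force is the signed cumulative integral of its
#' piecewise-linear stiffness from the reference position, and the net
#' proximal-distal LG+PL force difference is their signed sum
#' \eqn{\Delta F_{LGPL} = F_{INT} + F_{NV1} + F_{NV2}}. By construction
#' \eqn{\Delta F_{LGPL}(0) = 0} exactly.
#'
#' Optional per-segment scale factors `r` rescale the INT pathway only; they
#' model the reduced recruitment of the intermuscular tissue when only the
#' proximal LG+PL tendon is repositioned (see [predict_delta_f()]). With
#' `r = NULL` (calibration mode, both tendons repositioned) the INT pathway
#' is used as calibrated.
#'
#' @param set A [stiffness_set()].
#' @param position_mm Relative positions (mm) within the covered span.
#' @param r Optional numeric vector of per-segment INT scale factors
#'   (length = number of segments), or `NULL`.
#' @return A data frame with columns `position_mm`, `f_int_N`, `f_nv1_N`,
#'   `f_nv2_N` and `delta_f_lgpl_N`.
#' @export
forward_delta_f <- function(set, position_mm, r = NULL) {
  stopifnot(inherits(set, "stiffness_set"))
  int <- set$pathways$INT
  if (!is.null(r)) {
    nseg <- length(int$k_mN_mm)
    if (!is.numeric(r) || length(r) != nseg || !all(is.finite(r))) {
      stop("`r` must be a finite numeric vector with one value per segment (",
           nseg, ")", call. = FALSE)
    }
    int$k_mN_mm <- int$k_mN_mm * r
  }
  f_int <- pathway_force(int, position_mm)
  f_nv1 <- pathway_force(set$pathways$NV1, position_mm)
  f_nv2 <- pathway_force(set$pathways$NV2, position_mm)
  data.frame(position_mm = position_mm,
             f_int_N = f_int,
             f_nv1_N = f_nv1,
             f_nv2_N = f_nv2,
             delta_f_lgpl_N = f_int + f_nv1 + f_nv2)
}

#' Linear interpolation between two connectivity conditions
#'
#' Builds a stiffness set intermediate between normal (NO) and enhanced (TI)
#' connectivity by interpolating every segment stiffness (and `c`) linearly:
#' K(alpha) = (1 - alpha) K_NO + alpha K_TI. This provides a continuous
#' representation of progressive tissue integration (e.g. scar-tissue
#' development) between the two calibrated conditions.
#'
#' @param no_set,ti_set [stiffness_set()] objects sharing breakpoints.
#' @param alpha Interpolation weight in \[0, 1\]: 0 returns `no_set`'s values,
#'   1 returns `ti_set`'s.
#' @return A [stiffness_set()] with group `NA` (unless `alpha` is 0 or 1).
#' @export
interpolate_stiffness <- function(no_set, ti_set, alpha) {
  stopifnot(inherits(no_set, "stiffness_set"), inherits(ti_set, "stiffness_set"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  bp <- no_set$pathways$INT$breakpoints_mm
  if (!identical(bp, ti_set$pathways$INT$breakpoints_mm)) {
    stop("the two stiffness sets must share segment breakpoints",
         call. = FALSE)
  }
  mix <- function(a, b) (1 - alpha) * a + alpha * b
  paths <- lapply(c(INT = "INT", NV1 = "NV1", NV2 = "NV2"), function(nm) {
    a <- no_set$pathways[[nm]]
    b <- ti_set$pathways[[nm]]
    piecewise_stiffness(nm, mix(a$k_mN_mm, b$k_mN_mm), a$breakpoints_mm,
                        group = NA_character_,
                        symmetric = a$symmetric && b$symmetric)
  })
  group <- if (alpha == 0) no_set$group else if (alpha == 1) ti_set$group
           else NA_character_
  stiffness_set(paths$INT, paths$NV1, paths$NV2, group = group,
                c = mix(no_set$c, ti_set$c))
}

#' Bundled calibration stiffness estimates
#'
#' Returns the package's bundled piecewise stiffness estimates for the rat
#' SO and LG+PL preparation, for the normal-connectivity group (`"NO"`) or
#' the tissue-integrating-mesh group (`"TI"`), read from the YAML fixtures
#' shipped in `inst/extdata/`. NV2 carries the opposite sign to INT and NV1,
#' encoding the opposing direction of its force transmission vector.
#'
#' @param group `"NO"` or `"TI"`.
#' @return A [stiffness_set()], with the per-segment proximal-only scale
#'   factors attached as attribute `"r"`.
#' @export
#' @examples
#' forward_delta_f(bundled_stiffness("NO"), 3)
bundled_stiffness <- function(group = c("NO", "TI")) {
  group <- match.arg(group)
  path <- system.file("extdata",
                      paste0("stiffness_", tolower(group), ".yaml"),
                      package = "epimusc", mustWork = TRUE)
  read_stiffness_yaml(path)
}
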