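#' Estimate pathway forces from the three resection conditions
#'
#' Inverts the static force balances of the lumped model using the LG+PL
#' proximal-distal force differences measured in the intact, post-I
#' (intermuscular tissue resected) and post-II (additionally NV1 resected)
#' conditions:
#' \deqn{\hat F_{INT} = \Delta F^{intact} - c\,\Delta F^{postI} +
#'   (c - 1)\,\Delta F^{postII}}
#' \deqn{\hat F_{NV1} = \Delta F^{postI} - \Delta F^{postII}}
#' \deqn{\hat F_{NV2} = \Delta F^{postII}}
#' where `c` is the dimensionless NV1 length ratio before vs after resection
#' of the myofascial linkages (default 0.9). The algebraic identity
#' \eqn{\hat F_{INT} + \hat F_{NV1} + \hat F_{NV2} =
#' \Delta F^{intact} + (1 - c)\hat F_{NV1}} holds exactly.
#'
#' With `re_reference = TRUE` (default) each input series is first expressed
#' relative to its value at the reference position, so all estimates are
#' exactly zero at 0 mm even on noisy data; already-referenced inputs are
#' unchanged.
#'
#' @param d_intact,d_postI,d_postII Per-position \eqn{\Delta F_{LGPL}} series
#'   (N), aligned with `positions_mm`. `d_postII` may be a group-level series
#'   shared across animals.
#' @param positions_mm Protocol positions (mm), containing one 0.
#' @param c NV1 length-ratio parameter in (0, 1].
#' @param group Optional group label carried through to the result.
#' @param re_reference Subtract the reference-position value from every
#'   input series first (default `TRUE`).
#' @return A data frame of class `pathway_estimates` with columns
#'   `position_mm`, `f_int_N`, `f_nv1_N`, `f_nv2_N`; attributes `c` and
#'   `group`.
#' @export
#' @examples
#' estimate_pathway_forces(0.6, 0.15, 0.10, positions_mm = 0, c = 0.9,
#'                         re_reference = FALSE)
estimate_pathway_forces <- function(d_intact, d_postI, d_postII, positions_mm,
                                    c = 0.9, group = NA_character_,
                                    re_reference = TRUE) {
  check_c(c)
  n <- length(positions_mm)
  series <- list(d_intact = d_intact, d_postI = d_postI, d_postII = d_postII)
  for (nm in names(series)) {
    if (length(series[[nm]]) != n) {
      stop("`", nm, "` must have one value per position (", n, ")",
           call. = FALSE)
    }
    if (!is.numeric(series[[nm]]) || !all(is.finite(series[[nm]]))) {
      stop("`", nm, "` must be finite numeric", call. = FALSE)
    }
  }
  if (re_reference) {
    ref <- which(positions_mm == 0)
    if (length(ref) != 1L) {
      stop("`positions_mm` must contain exactly one reference position (0)",
           call. = FALSE)
    }
    series <- lapply(series, function(s) s - s[ref])
  }
  f_nv2 <- series$d_postII
  f_nv1 <- series$d_postI - series$d_postII
  f_int <- series$d_intact - c * series$d_postI + series$d_postII * (c - 1)
  structure(data.frame(position_mm = positions_mm,
                       f_int_N = f_int, f_nv1_N = f_nv1, f_nv2_N = f_nv2),
            c = c, group = group,
            class = c("pathway_estimates", "data.frame"))
}

est_column <- function(est, pathway) {
  est[[paste0("f_", tolower(pathway), "_N")]]
}

#' Fit piecewise-linear stiffness to per-position pathway force estimates
#'
#' For each pathway, the segment stiffness is the force increase over a unit
#' of relative displacement: \eqn{K_j = (\hat F(b_j) - \hat F(b_{j-1})) /
#' (b_j - b_{j-1})}. With `symmetry = TRUE` each segment stiffness is the
#' mean of the positive-side slope and the mirrored negative-side slope
#' (odd symmetry of the force-extension relation about the reference
#' position); with `symmetry = FALSE` only the positive side is used.
#'
#' @param estimates A [estimate_pathway_forces()] result (class
#'   `pathway_estimates`).
#' @param breakpoints_mm Segment breakpoints (mm), default `0:3`; all
#'   breakpoints (and their mirror images when `symmetry = TRUE`) must be
#'   protocol positions.
#' @param symmetry Average positive- and negative-side slopes (default
#'   `TRUE`).
#' @return A [stiffness_set()] with the fitted K values (mN/mm), carrying
#'   the `c` and group of the estimates.
#' @export
fit_piecewise_stiffness <- function(estimates, breakpoints_mm = 0:3,
                                    symmetry = TRUE) {
  if (!inherits(estimates, "pathway_estimates")) {
    stop("`estimates` must come from estimate_pathway_forces()",
         call. = FALSE)
  }
  if (any(diff(breakpoints_mm) <= 0) || breakpoints_mm[1L] != 0) {
    stop("`breakpoints_mm` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  pos <- estimates$position_mm
  need <- if (symmetry) sort(unique(c(breakpoints_mm, -breakpoints_mm)))
          else breakpoints_mm
  at <- match(need, pos)
  if (anyNA(at)) {
    stop("protocol positions are missing required breakpoint(s): ",
         paste(need[is.na(at)], collapse = ", "), " mm", call. = FALSE)
  }
  widths <- diff(breakpoints_mm)
  if (any(widths == 0)) stop("zero-width segment", call. = FALSE)
  fit_one <- function(pathway) {
    f <- est_column(estimates, pathway)
    f_at <- function(p) f[match(p, pos)]
    k_pos <- diff(f_at(breakpoints_mm)) / widths * 1000
    if (symmetry) {
      # slope over the mirrored segment [-b_j, -b_{j-1}], mapped by F(-P)=-F(P)
      k_neg <- (f_at(-breakpoints_mm[-length(breakpoints_mm)]) -
                  f_at(-breakpoints_mm[-1L])) / widths * 1000
      k <- (k_pos + k_neg) / 2
    } else {
      k <- k_pos
    }
    piecewise_stiffness(pathway, k, breakpoints_mm,
                        group = attr(estimates, "group"),
                        symmetric = symmetry)
  }
  stiffness_set(fit_one("INT"), fit_one("NV1"), fit_one("NV2"),
                group = attr(estimates, "group"), c = attr(estimates, "c"))
}

#' Sensitivity of the INT force estimate to the length-ratio parameter c
#'
#' Recomputes \eqn{\hat F_{INT}} over a grid of `c` values and reports, for
#' each, the root-mean-square deviation from the estimate at `c_ref`,
#' expressed as a percentage of the mean absolute INT force at `c_ref`.
#' Because \eqn{\hat F_{INT}} is affine in `c`, the curve equals the closed
#' form \eqn{|c - c_{ref}| \cdot RMS(\hat F_{NV1}) / mean|\hat F_{INT}|
#' \cdot 100}.
#'
#' @inheritParams estimate_pathway_forces
#' @param c_grid Grid of `c` values in (0, 1].
#' @param c_ref Reference value, default 0.9.
#' @return Data frame with columns `c` and `rmse_pct`.
#' @export
c_sensitivity <- function(d_intact, d_postI, d_postII, positions_mm,
                          c_grid = seq(0.05, 1, by = 0.05), c_ref = 0.9,
                          re_reference = TRUE) {
  ref <- estimate_pathway_forces(d_intact, d_postI, d_postII, positions_mm,
                                 c = c_ref, re_reference = re_reference)
  denom <- mean(abs(ref$f_int_N))
  if (denom == 0) {
    stop("mean |F_INT| at c_ref is zero; relative RMSE is undefined",
         call. = FALSE)
  }
  rmse_pct <- vapply(c_grid, function(cc) {
    est <- estimate_pathway_forces(d_intact, d_postI, d_postII, positions_mm,
                                   c = cc, re_reference = re_reference)
    sqrt(mean((est$f_int_N - ref$f_int_N)^2)) / denom * 100
  }, numeric(1L))
  data.frame(c = c_grid, rmse_pct = rmse_pct)
}

#' Per-segment scale factor r: proximal-only vs full-displacement loading
#'
#' When only the proximal LG+PL tendon is repositioned, the intermuscular
#' tissue is recruited less than when both tendons move together. The scale
#' factor is estimated per segment as the ratio of INT force transmitted per
#' unit displacement under proximal-only loading to that under full loading,
#' i.e. the elementwise ratio of segment stiffnesses.
#'
#' @param full INT [piecewise_stiffness()] (or numeric segment values) from
#'   the full calibration protocol.
#' @param proximal_only INT stiffness from the distal-only-resection subset,
#'   where only the proximal pathway is loaded; same segment structure.
#' @return Numeric vector, one `r` per segment.
#' @export
estimate_r <- function(full, proximal_only) {
  as_k <- function(x, what) {
    if (inherits(x, "piecewise_stiffness")) return(x$k_mN_mm)
    if (is.numeric(x)) return(as.numeric(x))
    stop("`", what, "` must be a piecewise_stiffness or numeric vector",
         call. = FALSE)
  }
  k_full <- as_k(full, "full")
  k_prox <- as_k(proximal_only, "proximal_only")
  if (length(k_full) != length(k_prox)) {
    stop("segment structures differ between the two inputs", call. = FALSE)
  }
  if (inherits(full, "piecewise_stiffness") &&
      inherits(proximal_only, "piecewise_stiffness") &&
      !identical(full$breakpoints_mm, proximal_only$breakpoints_mm)) {
    stop("segment breakpoints differ between the two inputs", call. = FALSE)
  }
  if (any(k_full == 0)) {
    stop("full-protocol segment stiffness is zero; ratio undefined",
         call. = FALSE)
  }
  k_prox / k_full
}

#' Pathway forces relative to the myotendinous (proximal tendon) force
#'
#' Expresses each estimated pathway force, and their signed sum, as a signed
#' percentage of the mean LG+PL proximal tendon force, describing how the
#' muscle's output is distributed between the myotendinous path and the
#' epimuscular pathways.
#'
#' @param estimates A `pathway_estimates` data frame.
#' @param f_prox_mean_N Mean LG+PL proximal tendon force (N), > 0.
#' @return Data frame with columns `position_mm`, `int_pct`, `nv1_pct`,
#'   `nv2_pct`, `net_pct`.
#' @export
pathway_ratios <- function(estimates, f_prox_mean_N = 11.5) {
  if (!inherits(estimates, "pathway_estimates")) {
    stop("`estimates` must come from estimate_pathway_forces()",
         call. = FALSE)
  }
  if (!is.numeric(f_prox_mean_N) || length(f_prox_mean_N) != 1L ||
      !is.finite(f_prox_mean_N) || f_prox_mean_N <= 0) {
    stop("`f_prox_mean_N` must be a single positive force", call. = FALSE)
  }
  pct <- function(f) 100 * f / f_prox_mean_N
  data.frame(position_mm = estimates$position_mm,
             int_pct = pct(estimates$f_int_N),
             nv1_pct = pct(estimates$f_nv1_N),
             nv2_pct = pct(estimates$f_nv2_N),
             net_pct = pct(estimates$f_int_N + estimates$f_nv1_N +
                             estimates$f_nv2_N))
}

#' Group-level stiffness estimation from a set of isometric tables
#'
#' Runs the full calibration pipeline on a collection of
#' [isometric_table()] objects from one group: per animal, the LG+PL force
#' differences of the three conditions are combined by
#' [estimate_pathway_forces()] (the post-II series is pooled across the
#' animals that have it, since complete isolation is typically feasible in
#' few animals) and piecewise stiffness is fitted; per-animal stiffness
#' estimates are then averaged across animals. Passive-state forces are
#' refused by default: the lumped model's force-matching assumption holds
#' only for the active state.
#'
#' @param tables List of [isometric_table()] objects (one group; intact and
#'   postI per animal, postII for at least one animal).
#' @param c NV1 length-ratio parameter.
#' @param symmetry Passed to [fit_piecewise_stiffness()].
#' @param breakpoints_mm Passed to [fit_piecewise_stiffness()].
#' @param state `"total"` (default). Using `"passive"` requires
#'   `allow_passive = TRUE` and warns.
#' @param allow_passive Override the refusal to model the passive state.
#' @return List with elements `mean` (a [stiffness_set()] of across-animal
#'   mean K values), `per_animal` (named list of per-animal stiffness sets)
#'   and `n` (number of animals).
#' @export
estimate_group_stiffness <- function(tables, c = 0.9, symmetry = TRUE,
                                     breakpoints_mm = 0:3, state = "total",
                                     allow_passive = FALSE) {
  stopifnot(is.list(tables), length(tables) > 0L)
  lapply(tables, check_isometric)
  if (state == "passive") {
    if (!allow_passive) {
      stop("stiffness estimation is not extended to the passive state ",
           "(the force-matching assumption fails there); set ",
           "`allow_passive = TRUE` to override", call. = FALSE)
    }
    warning("estimating epimuscular stiffness from passive forces: the ",
            "model's force-matching assumption does not hold in the ",
            "passive state", call. = FALSE)
  }
  groups <- unique(vapply(tables, function(x) attr(x, "group"), character(1L)))
  if (length(groups) != 1L) {
    stop("`tables` must all belong to one group; found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  cond <- vapply(tables, function(x) attr(x, "condition"), character(1L))
  animal <- vapply(tables, function(x) attr(x, "animal_id"), character(1L))
  pos <- tables[[1L]]$position_mm
  for (x in tables) {
    if (!identical(x$position_mm, pos)) {
      stop("all tables must share the same position protocol", call. = FALSE)
    }
  }
  post2_idx <- which(cond == "postII")
  if (length(post2_idx) == 0L) {
    stop("no post-II condition available in `tables`; the three-condition ",
         "estimator needs a (possibly group-level) post-II series",
         call. = FALSE)
  }
  d_post2 <- rowMeans(vapply(tables[post2_idx],
                             function(x) delta_f_lgpl(x, state),
                             numeric(length(pos))))
  fits <- list()
  for (a in unique(animal)) {
    i_int <- which(animal == a & cond == "intact")
    i_p1 <- which(animal == a & cond == "postI")
    if (length(i_int) != 1L || length(i_p1) != 1L) next
    est <- estimate_pathway_forces(delta_f_lgpl(tables[[i_int]], state),
                                   delta_f_lgpl(tables[[i_p1]], state),
                                   d_post2, pos, c = c, group = groups)
    fits[[a]] <- fit_piecewise_stiffness(est, breakpoints_mm, symmetry)
  }
  if (length(fits) == 0L) {
    stop("no animal has both an intact and a post-I table", call. = FALSE)
  }
  mean_k <- function(pathway) {
    rowMeans(vapply(fits, function(f) f$pathways[[pathway]]$k_mN_mm,
                    numeric(length(breakpoints_mm) - 1L)))
  }
  mean_set <- stiffness_set(
    piecewise_stiffness("INT", mean_k("INT"), breakpoints_mm, groups, symmetry),
    piecewise_stiffness("NV1", mean_k("NV1"), breakpoints_mm, groups, symmetry),
    piecewise_stiffness("NV2", mean_k("NV2"), breakpoints_mm, groups, symmetry),
    group = groups, c = c)
  list(mean = mean_set, per_animal = fits, n = length(fits))
}
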