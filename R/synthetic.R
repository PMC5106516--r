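#' Specification of a synthetic in situ experiment
#'
#' Collects everything needed to emulate the calibration and testing
#' protocols without animal data: ground-truth stiffness per group, the
#' per-segment proximal-only scale factors, baseline plateau and passive
#' forces, waveform timing, the noise model and the RNG seed. Defaults
#' reproduce the protocol conditions: tetanic plateaus of 11.5 N (LG+PL
#' proximal) and 1.3 N (SO distal) at the reference position, a 500-ms
#' tetanus preceded by two twitches 1.5 and 1.0 s earlier, positions -3 to
#' +3 mm in 1-mm steps, 7 animals per group, and additive Gaussian noise of
#' SD 0.05 N on each extracted force.
#'
#' @param truth Named list of ground-truth [stiffness_set()] objects per
#'   group; defaults to the bundled calibration estimates for NO and TI.
#' @param r Per-segment proximal-only scale factors for the testing
#'   protocol.
#' @param positions_mm Calibration/testing positions (mm).
#' @param baseline_lgpl_N,baseline_so_N Tetanic plateau forces at the
#'   reference position (N).
#' @param passive_lgpl_N,passive_so_N Passive baseline forces (N).
#' @param so_coupling Fraction of the epimuscular force routed onto the SO
#'   distal tendon (the remainder leaves via the intact SO proximal tendon
#'   and other unmeasured structures). Default 0.35.
#' @param noise_sd_N Additive Gaussian noise SD per extracted force (N).
#' @param n_animals Animals per group.
#' @param n_postII Number of animals per group receiving the complete
#'   isolation (post-II) condition; default 1, as complete isolation is
#'   rarely feasible.
#' @param postII_source `"own"` (post-II generated from the group's own
#'   ground truth) or `"borrow_no"` (TI reuses the NO post-II series, as
#'   when the TI neurovascular tract cannot be isolated surgically).
#' @param seed RNG seed (integer).
#' @param fs_hz Waveform sampling rate (Hz). Default 1000.
#' @param stim_onset_s,stim_duration_s Tetanus onset and duration (s).
#' @param twitch_offsets_s Twitch onsets, expressed as time before the
#'   tetanus onset (s).
#' @param twitch_duration_s Twitch transient duration (s).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(truth = list(NO = bundled_stiffness("NO"),
                                        TI = bundled_stiffness("TI")),
                           r = c(0.07, 0.13, 0.21),
                           positions_mm = -3:3,
                           baseline_lgpl_N = 11.5, baseline_so_N = 1.3,
                           passive_lgpl_N = 0.3, passive_so_N = 0.1,
                           so_coupling = 0.35,
                           noise_sd_N = 0.05, n_animals = 7L, n_postII = 1L,
                           postII_source = c("own", "borrow_no"),
                           seed = 1L, fs_hz = 1000,
                           stim_onset_s = 2.0, stim_duration_s = 0.5,
                           twitch_offsets_s = c(1.5, 1.0),
                           twitch_duration_s = 0.1) {
  postII_source <- match.arg(postII_source)
  stopifnot(is.list(truth), length(truth) >= 1L, !is.null(names(truth)))
  for (g in names(truth)) {
    if (!inherits(truth[[g]], "stiffness_set")) {
      stop("`truth$", g, "` must be a stiffness_set", call. = FALSE)
    }
  }
  if (!is.numeric(noise_sd_N) || noise_sd_N < 0) {
    stop("`noise_sd_N` must be >= 0", call. = FALSE)
  }
  if (n_animals < 1L || n_postII < 0L || n_postII > n_animals) {
    stop("need `n_animals` >= 1 and 0 <= `n_postII` <= `n_animals`",
         call. = FALSE)
  }
  if (any(c(baseline_lgpl_N, baseline_so_N, passive_lgpl_N, passive_so_N) <= 0)) {
    stop("baseline forces must be positive", call. = FALSE)
  }
  if (so_coupling < 0 || so_coupling > 1) {
    stop("`so_coupling` must be in [0, 1]", call. = FALSE)
  }
  protocol <- position_protocol(positions_mm)
  # the passive extraction window (50 ms) must be clear of twitch transients
  if (any(twitch_offsets_s - twitch_duration_s < 0.05)) {
    stop("a twitch transient would overlap the passive extraction window; ",
         "twitch offsets must exceed their duration by >= 50 ms",
         call. = FALSE)
  }
  if (stim_onset_s <= max(twitch_offsets_s)) {
    stop("twitches must occur after the start of the recording",
         call. = FALSE)
  }
  structure(list(truth = truth, r = as.numeric(r),
                 positions_mm = protocol$positions_mm,
                 baseline_lgpl_N = baseline_lgpl_N,
                 baseline_so_N = baseline_so_N,
                 passive_lgpl_N = passive_lgpl_N,
                 passive_so_N = passive_so_N,
                 so_coupling = so_coupling,
                 noise_sd_N = noise_sd_N,
                 n_animals = as.integer(n_animals),
                 n_postII = as.integer(n_postII),
                 postII_source = postII_source,
                 seed = as.integer(seed), fs_hz = fs_hz,
                 stim_onset_s = stim_onset_s,
                 stim_duration_s = stim_duration_s,
                 twitch_offsets_s = as.numeric(twitch_offsets_s),
                 twitch_duration_s = twitch_duration_s),
            class = "synthetic_spec")
}

# Noise-free per-position force differences implied by a ground truth for
# one resection condition. The intact condition carries c * F_NV1 (NV1 in
# its pre-resection, shorter state), post I carries F_NV1 + F_NV2 (NV1 in
# the post-resection state whose stiffness the estimator recovers), post II
# only F_NV2 -- so the three-condition estimator inverts these exactly.
# The SO distal channel receives the coupling fraction of the force routed
# towards SO (INT and NV1); NV2 routes outside the SO/LG+PL pair.
condition_deltas <- function(truth, positions_mm, condition, so_coupling) {
  fw <- forward_delta_f(truth, positions_mm)
  cc <- truth$c
  switch(condition,
    intact = list(d_lgpl = fw$f_int_N + cc * fw$f_nv1_N + fw$f_nv2_N,
                  d_so = so_coupling * (fw$f_int_N + cc * fw$f_nv1_N)),
    postI = list(d_lgpl = fw$f_nv1_N + fw$f_nv2_N,
                 d_so = so_coupling * fw$f_nv1_N),
    postII = list(d_lgpl = fw$f_nv2_N,
                  d_so = rep(0, length(positions_mm))),
    stop("unknown condition: ", condition, call. = FALSE))
}

# Assemble one noisy isometric table from noise-free deltas.
synth_table <- function(spec, d, positions_mm, condition, group, animal_id,
                        mode = "calibration") {
  n <- length(positions_mm)
  noise <- function() stats::rnorm(n, sd = spec$noise_sd_N)
  total <- data.frame(
    so_dist = spec$baseline_so_N + d$d_so + noise(),
    lgpl_prox = spec$baseline_lgpl_N + d$d_lgpl / 2 + noise(),
    lgpl_dist = spec$baseline_lgpl_N - d$d_lgpl / 2 + noise())
  passive <- data.frame(
    so_dist = spec$passive_so_N + noise(),
    lgpl_prox = spec$passive_lgpl_N + noise(),
    lgpl_dist = spec$passive_lgpl_N + noise())
  isometric_table(positions_mm, passive, total, condition = condition,
                  group = group, animal_id = animal_id, mode = mode)
}

#' Synthesise a stimulation waveform for one trial
#'
#' Builds the schematic force-time series of one contraction: passive
#' baseline, two conditioning twitch transients, a smooth rise to the
#' tetanic plateau (whose level encodes the position- and
#' condition-dependent forces implied by the ground-truth stiffness), and
#' an exponential relaxation, plus per-sample Gaussian noise. Applying
#' [extract_isometric()] to the noiseless waveform returns the configured
#' passive and total forces exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param position_mm Relative position (mm) of the trial.
#' @param condition Resection condition.
#' @param group Group label (must name an entry of `spec$truth`).
#' @return A [force_waveform()].
#' @export
generate_waveform <- function(spec, position_mm,
                              condition = c("intact", "postI", "postII"),
                              group = "NO") {
  stopifnot(inherits(spec, "synthetic_spec"))
  condition <- match.arg(condition)
  truth <- spec$truth[[group]]
  if (is.null(truth)) stop("no ground truth for group ", group, call. = FALSE)
  set.seed(spec$seed)
  d <- condition_deltas(truth, position_mm, condition, spec$so_coupling)
  passive <- c(so_dist = spec$passive_so_N,
               lgpl_prox = spec$passive_lgpl_N,
               lgpl_dist = spec$passive_lgpl_N)
  total <- c(so_dist = spec$baseline_so_N + d$d_so,
             lgpl_prox = spec$baseline_lgpl_N + d$d_lgpl / 2,
             lgpl_dist = spec$baseline_lgpl_N - d$d_lgpl / 2)
  onset <- spec$stim_onset_s
  offset <- onset + spec$stim_duration_s
  t_end <- offset + 0.5
  t <- seq(0, t_end, by = 1 / spec$fs_hz)
  rise <- 0.02   # s, completes well before the plateau window
  tau <- 0.05    # s, relaxation time constant
  activation <- numeric(length(t))
  in_rise <- t >= onset & t < onset + rise
  activation[in_rise] <- 0.5 * (1 - cos(pi * (t[in_rise] - onset) / rise))
  activation[t >= onset + rise & t <= offset] <- 1
  post <- t > offset
  activation[post] <- exp(-(t[post] - offset) / tau)
  twitch <- numeric(length(t))
  for (off in spec$twitch_offsets_s) {
    t0 <- onset - off
    in_tw <- t >= t0 & t <= t0 + spec$twitch_duration_s
    twitch[in_tw] <- twitch[in_tw] +
      sin(pi * (t[in_tw] - t0) / spec$twitch_duration_s)^2
  }
  chan <- function(nm) {
    amp <- total[[nm]] - passive[[nm]]
    passive[[nm]] + amp * activation + 0.25 * amp * twitch +
      stats::rnorm(length(t), sd = spec$noise_sd_N)
  }
  force_waveform(t, chan("so_dist"), chan("lgpl_prox"), chan("lgpl_dist"),
                 stim_onset_s = onset, stim_offset_s = offset,
                 twitch_times_s = onset - spec$twitch_offsets_s,
                 twitch_duration_s = spec$twitch_duration_s)
}

#' Generate a synthetic calibration dataset
#'
#' Emulates the three-condition calibration experiment: for each group and
#' animal, isometric force tables for the intact and post-I conditions, and
#' for the first `n_postII` animals also the post-II (complete isolation)
#' condition. Identical spec and seed give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @param groups Which groups to generate (default: all groups in
#'   `spec$truth`).
#' @return A flat list of [isometric_table()] objects.
#' @export
generate_calibration_dataset <- function(spec, groups = names(spec$truth)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  pos <- spec$positions_mm
  out <- list()
  for (g in groups) {
    truth <- spec$truth[[g]]
    if (is.null(truth)) stop("no ground truth for group ", g, call. = FALSE)
    p2_truth <- if (spec$postII_source == "borrow_no" && g == "TI") {
      if (is.null(spec$truth$NO)) {
        stop("postII_source = \"borrow_no\" requires an NO ground truth",
             call. = FALSE)
      }
      spec$truth$NO
    } else truth
    for (a in seq_len(spec$n_animals)) {
      id <- paste0(tolower(g), a)
      conds <- c("intact", "postI", if (a <= spec$n_postII) "postII")
      for (cond in conds) {
        tr <- if (cond == "postII") p2_truth else truth
        d <- condition_deltas(tr, pos, cond, spec$so_coupling)
        out[[paste(id, cond, sep = "_")]] <-
          synth_table(spec, d, pos, cond, g, id)
      }
    }
  }
  out
}

#' Generate a synthetic testing dataset (proximal-only repositioning)
#'
#' Emulates the testing protocol in which only the LG+PL proximal tendon is
#' repositioned: the noise-free force difference follows the proximal-only
#' forward model (INT scaled by the per-segment factors `r`, zero offset at
#' the reference position), and the SO channel receives the coupled INT and
#' NV1 share.
#'
#' @inheritParams generate_calibration_dataset
#' @return A flat list of [isometric_table()] objects with testing-mode
#'   protocols (condition label `"intact"`: no resection is performed in
#'   the testing experiment).
#' @export
generate_testing_dataset <- function(spec, groups = names(spec$truth)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$r) || length(spec$r) == 0L) {
    stop("the testing protocol requires per-segment `r` factors in the spec",
         call. = FALSE)
  }
  set.seed(spec$seed + 1L)
  pos <- spec$positions_mm
  out <- list()
  for (g in groups) {
    truth <- spec$truth[[g]]
    if (is.null(truth)) stop("no ground truth for group ", g, call. = FALSE)
    fw <- forward_delta_f(truth, pos, r = spec$r)
    d <- list(d_lgpl = fw$delta_f_lgpl_N,
              d_so = spec$so_coupling * (fw$f_int_N + truth$c * fw$f_nv1_N))
    for (a in seq_len(spec$n_animals)) {
      id <- paste0(tolower(g), a)
      out[[paste(id, "testing", sep = "_")]] <-
        synth_table(spec, d, pos, "intact", g, id, mode = "testing")
    }
  }
  out
}
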