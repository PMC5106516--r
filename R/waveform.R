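#' Tendon force recording for one contraction
#'
#' A uniformly sampled multi-channel force-time series for one stimulation
#' trial: SO distal, LG+PL proximal and LG+PL distal tendon forces, with the
#' tetanic stimulation window and the times of the conditioning twitches
#' evoked before the tetanus.
#'
#' @param time_s Strictly increasing, uniformly sampled time vector (s).
#' @param f_so_dist_N,f_lgpl_prox_N,f_lgpl_dist_N Force channels (N), same
#'   length as `time_s`.
#' @param stim_onset_s,stim_offset_s Tetanic stimulation onset/offset (s),
#'   inside the recording.
#' @param twitch_times_s Onset times of the conditioning twitches (s);
#'   default two twitches 1.5 and 1.0 s before the tetanus.
#' @param twitch_duration_s Nominal duration of a twitch transient (s),
#'   used to guard the passive extraction window. Default 0.1.
#' @return An object of class `force_waveform`.
#' @export
force_waveform <- function(time_s, f_so_dist_N, f_lgpl_prox_N, f_lgpl_dist_N,
                           stim_onset_s, stim_offset_s,
                           twitch_times_s = stim_onset_s - c(1.5, 1.0),
                           twitch_duration_s = 0.1) {
  n <- length(time_s)
  if (n < 2L || !all(is.finite(time_s))) {
    stop("`time_s` must be a finite vector of length >= 2", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0) || max(abs(dt - dt[1L])) > 1e-9 * dt[1L] + 1e-12) {
    stop("`time_s` must be strictly increasing and uniformly sampled",
         call. = FALSE)
  }
  forces <- list(so_dist = f_so_dist_N, lgpl_prox = f_lgpl_prox_N,
                 lgpl_dist = f_lgpl_dist_N)
  for (nm in names(forces)) {
    if (length(forces[[nm]]) != n || !all(is.finite(forces[[nm]]))) {
      stop("channel `", nm, "` must be finite and match `time_s` in length",
           call. = FALSE)
    }
  }
  if (!(stim_onset_s >= time_s[1L] && stim_offset_s <= time_s[n] &&
        stim_offset_s > stim_onset_s)) {
    stop("stimulation window must lie inside the recording", call. = FALSE)
  }
  structure(list(time_s = as.numeric(time_s),
                 forces = lapply(forces, as.numeric),
                 stim_onset_s = stim_onset_s,
                 stim_offset_s = stim_offset_s,
                 twitch_times_s = as.numeric(twitch_times_s),
                 twitch_duration_s = twitch_duration_s),
            class = "force_waveform")
}

#' @export
print.force_waveform <- function(x, ...) {
  cat("Force waveform: ", length(x$time_s), " samples, ",
      format(1 / diff(x$time_s[1:2])), " Hz; tetanus [",
      x$stim_onset_s, ", ", x$stim_offset_s, "] s; twitches at ",
      paste(x$twitch_times_s, collapse = ", "), " s\n", sep = "")
  invisible(x)
}

#' Extract passive and total isometric forces from a waveform
#'
#' Passive force is the mean over a window immediately preceding the tetanic
#' stimulation onset; total force is the mean over the final window of the
#' tetanic stimulation (the plateau). Both windows default to 50 ms. If a
#' conditioning twitch transient overlaps the passive window, the window is
#' shifted earlier to end at the twitch onset, with a warning.
#'
#' @param waveform A [force_waveform()].
#' @param window_ms Window length, ms. Default 50.
#' @return A list with named numeric vectors `passive` and `total` (one
#'   entry per channel: `so_dist`, `lgpl_prox`, `lgpl_dist`), plus the
#'   `passive_window_s` and `total_window_s` actually used.
#' @export
extract_isometric <- function(waveform, window_ms = 50) {
  if (!inherits(waveform, "force_waveform")) {
    stop("`waveform` must be a force_waveform object", call. = FALSE)
  }
  if (!is.numeric(window_ms) || window_ms <= 0) {
    stop("`window_ms` must be a positive duration", call. = FALSE)
  }
  w <- window_ms / 1000
  t <- waveform$time_s
  if (waveform$stim_offset_s - waveform$stim_onset_s < w) {
    stop("tetanic stimulation shorter than the extraction window",
         call. = FALSE)
  }
  passive_end <- waveform$stim_onset_s
  # shift the passive window clear of any twitch transient overlapping it
  repeat {
    pw <- c(passive_end - w, passive_end)
    tw_end <- waveform$twitch_times_s + waveform$twitch_duration_s
    hit <- waveform$twitch_times_s < pw[2L] & tw_end > pw[1L]
    if (!any(hit)) break
    shifted_to <- min(waveform$twitch_times_s[hit])
    warning("twitch transient overlaps the passive window; window shifted ",
            "to end at t = ", format(shifted_to), " s", call. = FALSE)
    passive_end <- shifted_to
  }
  if (passive_end - w < t[1L]) {
    stop("not enough pre-stimulation data for a ", window_ms,
         " ms passive window", call. = FALSE)
  }
  pw <- c(passive_end - w, passive_end)
  tw <- c(waveform$stim_offset_s - w, waveform$stim_offset_s)
  in_pw <- t >= pw[1L] & t < pw[2L]
  in_tw <- t >= tw[1L] & t <= tw[2L]
  if (!any(in_pw) || !any(in_tw)) {
    stop("extraction window contains no samples", call. = FALSE)
  }
  win_mean <- function(idx) {
    vapply(waveform$forces, function(f) mean(f[idx]), numeric(1L))
  }
  list(passive = win_mean(in_pw), total = win_mean(in_tw),
       passive_window_s = pw, total_window_s = tw)
}
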