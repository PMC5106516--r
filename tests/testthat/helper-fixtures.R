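# Fixture builders shared across test files. All synthetic; no data files.

# A small all-positive-stiffness ground truth for guard-railed invariants.
toy_truth <- function(k_int = c(300, 200, 100), k_nv1 = c(50, 10, 20),
                      k_nv2 = c(40, 20, 10), group = "NO", c = 0.9) {
  stiffness_set(piecewise_stiffness("INT", k_int, group = group),
                piecewise_stiffness("NV1", k_nv1, group = group),
                piecewise_stiffness("NV2", k_nv2, group = group),
                group = group, c = c)
}

group_tables <- function(tables, g) {
  Filter(function(x) attr(x, "group") == g, tables)
}

# Hand-built waveform: constant passive level, constant plateau, instant
# transitions outside the extraction windows.
flat_waveform <- function(passive = 1.0, plateau = 5.0, fs = 1000,
                          onset = 2.0, offset = 2.5, t_end = 3.0,
                          twitch_times = onset - c(1.5, 1.0)) {
  t <- seq(0, t_end, by = 1 / fs)
  f <- ifelse(t >= onset & t <= offset, plateau, passive)
  force_waveform(t, f, f, f, stim_onset_s = onset, stim_offset_s = offset,
                 twitch_times_s = twitch_times)
}

# Pathway estimates data frame built directly from per-position forces (N).
manual_estimates <- function(positions_mm, f_int, f_nv1 = 0 * f_int,
                             f_nv2 = 0 * f_int, c = 0.9, group = "NO") {
  structure(data.frame(position_mm = positions_mm, f_int_N = f_int,
                       f_nv1_N = f_nv1, f_nv2_N = f_nv2),
            c = c, group = group,
            class = c("pathway_estimates", "data.frame"))
}
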