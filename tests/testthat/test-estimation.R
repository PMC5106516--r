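test_that("isometric extraction averages the correct 50-ms windows", {
  wf <- flat_waveform(passive = 1.0, plateau = 5.0)
  ex <- extract_isometric(wf)
  expect_equal(unname(ex$passive), rep(1.0, 3))
  expect_equal(unname(ex$total), rep(5.0, 3))

  # linear ramp over the final window averages to its midpoint value
  wf2 <- flat_waveform(passive = 1.0, plateau = 5.0)
  idx <- wf2$time_s >= 2.45 & wf2$time_s <= 2.5
  ramp <- seq(4.9, 5.1, length.out = sum(idx))
  for (ch in names(wf2$forces)) wf2$forces[[ch]][idx] <- ramp
  expect_equal(unname(extract_isometric(wf2)$total), rep(5.0, 3))

  # generator round trip at the configured plateau
  spec <- synthetic_spec(noise_sd_N = 0)
  w <- generate_waveform(spec, 0, "intact", "NO")
  ex3 <- extract_isometric(w)
  expect_equal(unname(ex3$total["lgpl_prox"]), 11.5)
  expect_equal(unname(ex3$total["so_dist"]), 1.3)
})

test_that("extraction guards its windows", {
  wf <- flat_waveform()
  expect_error(extract_isometric(wf, window_ms = 600), "shorter")
  # a twitch inside the passive window shifts the window with a warning
  wf_tw <- flat_waveform(twitch_times = c(0.5, 1.98))
  expect_warning(ex <- extract_isometric(wf_tw), "shifted")
  expect_lte(ex$passive_window_s[2], 1.98)
  expect_equal(unname(ex$passive), rep(1.0, 3))
  # window longer than the pre-stimulation data
  short <- flat_waveform(onset = 0.04, offset = 0.6, t_end = 1,
                         twitch_times = numeric())
  expect_error(extract_isometric(short), "pre-stimulation")
})

test_that("tendon force differences follow their definitions", {
  tab <- isometric_table(
    c(-1, 0, 1),
    passive = data.frame(so_dist = rep(0.1, 3), lgpl_prox = rep(0.3, 3),
                         lgpl_dist = rep(0.3, 3)),
    total = data.frame(so_dist = c(1.0, 1.3, 1.6),
                       lgpl_prox = c(11.0, 11.5, 12.0),
                       lgpl_dist = c(11.4, 11.5, 11.5)),
    condition = "intact", group = "NO")
  expect_equal(delta_f_lgpl(tab), c(-0.4, 0, 0.5))
  expect_equal(delta_f_so(tab), c(-0.3, 0, 0.3))
  expect_equal(delta_f_so(tab)[2], 0)

  const <- tab
  const$total_so_dist_N <- rep(1.3, 3)
  expect_equal(delta_f_so(const), rep(0, 3))

  broken <- tab
  broken$total_lgpl_dist_N <- NULL
  expect_error(delta_f_lgpl(broken), "total_lgpl_dist_N")
})

test_that("table constructor validates and normalises", {
  expect_error(
    isometric_table(c(0, 1),
                    passive = data.frame(so_dist = c(2, 2), lgpl_prox = 0:1,
                                         lgpl_dist = 0:1),
                    total = data.frame(so_dist = c(1, 3), lgpl_prox = 1:2,
                                       lgpl_dist = 1:2)),
    "passive force exceeds total")
  shuffled <- isometric_table(
    c(1, -1, 0),
    passive = data.frame(so_dist = c(1, 3, 2) / 10, lgpl_prox = rep(0.1, 3),
                         lgpl_dist = rep(0.1, 3)),
    total = data.frame(so_dist = c(10, 30, 20), lgpl_prox = rep(11, 3),
                       lgpl_dist = rep(11, 3)))
  expect_equal(shuffled$position_mm, c(-1, 0, 1))
  expect_equal(shuffled$total_so_dist_N, c(30, 20, 10))
})

test_that("three-condition estimator matches the closed-form equations", {
  est <- estimate_pathway_forces(0.6, 0.15, 0.10, positions_mm = 0, c = 0.9,
                                 re_reference = FALSE)
  expect_equal(est$f_int_N, 0.455)
  expect_equal(est$f_nv1_N, 0.05)
  expect_equal(est$f_nv2_N, 0.10)

  # c = 1 limit: INT is the plain intact-minus-postI difference
  est1 <- estimate_pathway_forces(0.6, 0.15, 0.10, positions_mm = 0, c = 1,
                                  re_reference = FALSE)
  expect_equal(est1$f_int_N, 0.6 - 0.15)

  z <- estimate_pathway_forces(rep(0, 3), rep(0, 3), rep(0, 3),
                               positions_mm = -1:1)
  expect_equal(unlist(z[, -1]), rep(0, 9), ignore_attr = TRUE)

  expect_error(estimate_pathway_forces(1, 1, 1, positions_mm = 0, c = 0),
               "\\(0, 1\\]")
  expect_error(estimate_pathway_forces(1:3, 1:2, 1:3, positions_mm = 1:3),
               "per position")
})

test_that("estimator conservation and linearity hold for arbitrary inputs", {
  set.seed(11)
  pos <- -3:3
  for (i in 1:25) {
    cc <- runif(1, 0.05, 1)
    di <- rnorm(7); d1 <- rnorm(7); d2 <- rnorm(7)
    est <- estimate_pathway_forces(di, d1, d2, pos, c = cc,
                                   re_reference = FALSE)
    # conservation: sum of estimates minus (1-c) NV1 returns the intact series
    expect_equal(est$f_int_N + est$f_nv1_N + est$f_nv2_N -
                   (1 - cc) * est$f_nv1_N, di)
    # superposition against a brute-force second evaluation
    ei <- rnorm(7); e1 <- rnorm(7); e2 <- rnorm(7)
    est_b <- estimate_pathway_forces(ei, e1, e2, pos, c = cc,
                                     re_reference = FALSE)
    est_ab <- estimate_pathway_forces(di + ei, d1 + e1, d2 + e2, pos, c = cc,
                                      re_reference = FALSE)
    for (col in c("f_int_N", "f_nv1_N", "f_nv2_N")) {
      expect_equal(est_ab[[col]], est[[col]] + est_b[[col]])
    }
  }
})

test_that("re-referencing pins all estimates to zero at the reference", {
  set.seed(3)
  pos <- -3:3
  est <- estimate_pathway_forces(rnorm(7), rnorm(7), rnorm(7), pos, c = 0.8)
  ref <- which(pos == 0)
  expect_equal(est$f_int_N[ref], 0)
  expect_equal(est$f_nv1_N[ref], 0)
  expect_equal(est$f_nv2_N[ref], 0)
})

test_that("piecewise stiffness fit inverts the forward model", {
  no <- bundled_stiffness("NO")
  pos <- -3:3
  fw <- forward_delta_f(no, pos)
  est <- manual_estimates(pos, fw$f_int_N, fw$f_nv1_N, fw$f_nv2_N)
  fit <- fit_piecewise_stiffness(est)
  expect_equal(segment_stiffness(fit), segment_stiffness(no),
               tolerance = 1e-12)

  # pure linear force gives constant stiffness
  lin <- manual_estimates(pos, 100 * pos / 1000)
  expect_equal(fit_piecewise_stiffness(lin)$pathways$INT$k_mN_mm,
               c(100, 100, 100))
})

test_that("symmetry averaging takes the mean of mirrored slopes", {
  pos <- -3:3
  # positive slope 200 mN/mm on [0,1]; mirrored negative slope 220 mN/mm
  f_int <- c(-0.62, -0.42, -0.22, 0, 0.2, 0.4, 0.6)
  est <- manual_estimates(pos, f_int)
  fit <- fit_piecewise_stiffness(est, symmetry = TRUE)
  expect_equal(fit$pathways$INT$k_mN_mm[1], 210)
  fit_pos <- fit_piecewise_stiffness(est, symmetry = FALSE)
  expect_equal(fit_pos$pathways$INT$k_mN_mm[1], 200)

  sparse <- manual_estimates(c(-3, 0, 1, 2, 3), c(-1, 0, 0.1, 0.2, 0.3))
  expect_error(fit_piecewise_stiffness(sparse, symmetry = TRUE), "missing")
  expect_error(fit_piecewise_stiffness(sparse, symmetry = FALSE), NA)
})

test_that("c-sensitivity equals its closed form", {
  set.seed(5)
  pos <- -3:3
  di <- cumsum(rnorm(7)); d1 <- cumsum(rnorm(7)); d2 <- cumsum(rnorm(7))
  di <- di - di[4]; d1 <- d1 - d1[4]; d2 <- d2 - d2[4]
  grid <- seq(0.05, 1, by = 0.05)
  sens <- c_sensitivity(di, d1, d2, pos, c_grid = grid, c_ref = 0.9)
  ref <- estimate_pathway_forces(di, d1, d2, pos, c = 0.9)
  rms_nv1 <- sqrt(mean(ref$f_nv1_N^2))
  closed <- abs(grid - 0.9) * rms_nv1 / mean(abs(ref$f_int_N)) * 100
  expect_equal(sens$rmse_pct, closed, tolerance = 1e-9)
  expect_equal(c_sensitivity(di, d1, d2, pos, c_grid = 0.9)$rmse_pct, 0)

  # postI == postII makes the INT estimate independent of c
  same <- c_sensitivity(di, d1, d1, pos, c_grid = grid)
  expect_equal(same$rmse_pct, rep(0, length(grid)))

  expect_error(c_sensitivity(rep(0, 7), rep(0, 7), rep(0, 7), pos),
               "undefined")
})

test_that("proximal-only scale factors are per-segment stiffness ratios", {
  full <- piecewise_stiffness("INT", c(239.8, 171.7, 143.9))
  prox <- piecewise_stiffness("INT",
                              c(239.8, 171.7, 143.9) * c(0.07, 0.13, 0.21))
  expect_equal(estimate_r(full, prox), c(0.07, 0.13, 0.21))
  expect_equal(estimate_r(full, full), c(1, 1, 1))
  expect_error(estimate_r(piecewise_stiffness("INT", c(0, 1, 2)), full),
               "zero")
  expect_error(estimate_r(full, c(1, 2)), "differ")
})

test_that("pathway ratios scale forces by the mean proximal tendon force", {
  est <- manual_estimates(0, 1.15)
  expect_equal(pathway_ratios(est, 11.5)$int_pct, 10)
  expect_equal(pathway_ratios(manual_estimates(0, 0), 11.5)$int_pct, 0)
  expect_error(pathway_ratios(est, 0), "positive")

  ti <- bundled_stiffness("TI")
  fw <- forward_delta_f(ti, -3:3)
  est_ti <- manual_estimates(-3:3, fw$f_int_N, fw$f_nv1_N, fw$f_nv2_N,
                             group = "TI")
  net <- pathway_ratios(est_ti, 11.5)$net_pct
  expect_equal(net[7], 2.058 / 11.5 * 100)
})

test_that("group estimation refuses the passive state unless overridden", {
  spec <- synthetic_spec(noise_sd_N = 0, n_animals = 2)
  tabs <- group_tables(generate_calibration_dataset(spec, "NO"), "NO")
  expect_error(estimate_group_stiffness(tabs, state = "passive"),
               "passive")
  expect_warning(
    fit <- estimate_group_stiffness(tabs, state = "passive",
                                    allow_passive = TRUE),
    "passive")
  # passive forces are position-independent in the emulator: zero stiffness
  expect_equal(max(abs(segment_stiffness(fit$mean))), 0)
})
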