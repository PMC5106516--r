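test_that("node residuals implement the two static force balances", {
  # proximal node cancels by construction
  s <- node_state(f_prox = 11.5, f_dist = 11.0, f_muscle = 11.3,
                  f_int = 0.25, f_nv1 = 0.05, f_nv2 = 0.2)
  r <- node_residuals(s)
  expect_equal(unname(r["node_proximal"]), 0)
  expect_equal(unname(r["node_distal"]), 11.0 - 11.3 + 0.25 + 0.05)
  expect_equal(unname(r["node_distal"]), 0)

  zero <- node_state(0, 0, 0, 0, 0, 0)
  expect_equal(unname(node_residuals(zero)), c(0, 0))

  # difference of residuals = measured difference minus summed pathway forces
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(6)
    s <- node_state(v[1], v[2], v[3], v[4], v[5], v[6])
    r <- node_residuals(s)
    expect_equal(unname(r[1] - r[2]),
                 (v[1] - v[2]) - (v[6] + v[4] + v[5]))
  }
  expect_error(node_state(Inf, 0, 0, 0, 0, 0), "finite")
})

test_that("equilibrium states built from the forward model have zero residuals", {
  set <- bundled_stiffness("NO")
  set.seed(7)
  for (p in c(-2.5, -1, 0.5, 2, 3)) {
    fw <- forward_delta_f(set, p)
    f_muscle <- runif(1, 5, 15)
    st <- node_state(f_prox = f_muscle + fw$f_nv2_N,
                     f_dist = f_muscle - fw$f_int_N - fw$f_nv1_N,
                     f_muscle = f_muscle,
                     f_int = fw$f_int_N, f_nv1 = fw$f_nv1_N,
                     f_nv2 = fw$f_nv2_N)
    expect_lt(max(abs(node_residuals(st))), 1e-9)
  }
})

test_that("forward model reconstructs the calibrated force differences", {
  no <- bundled_stiffness("NO")
  # signed cumulative sum over the three 1-mm segments, NV2 opposing
  expect_equal(forward_delta_f(no, 3)$delta_f_lgpl_N,
               (239.8 + 171.7 + 143.9 + 21.7 + 0.4 + 34.6 -
                  56.6 - 30.8 - 17.1) / 1000)
  expect_equal(forward_delta_f(no, 1)$delta_f_lgpl_N,
               (239.8 + 21.7 - 56.6) / 1000)
  expect_identical(forward_delta_f(no, 0)$delta_f_lgpl_N, 0)
})

test_that("forward model is piecewise linear, odd-symmetric and additive", {
  no <- bundled_stiffness("NO")
  f <- function(p) forward_delta_f(no, p)$delta_f_lgpl_N
  # linear within each segment: midpoint equals mean of segment endpoints
  for (seg in list(c(0, 1), c(1, 2), c(2, 3))) {
    expect_equal(f(mean(seg)), (f(seg[1]) + f(seg[2])) / 2)
  }
  # odd symmetry and continuity across the reference
  grid <- seq(0, 3, by = 0.25)
  expect_equal(f(-grid), -f(grid))
  # additivity: zeroing one pathway removes exactly its contribution
  fw <- forward_delta_f(no, seq(-3, 3, by = 0.5))
  zeroed <- no
  zeroed$pathways$NV2$k_mN_mm[] <- 0
  fw0 <- forward_delta_f(zeroed, seq(-3, 3, by = 0.5))
  expect_equal(fw$delta_f_lgpl_N - fw0$delta_f_lgpl_N, fw$f_nv2_N)
  expect_equal(fw0$f_nv2_N, rep(0, nrow(fw0)))
})

test_that("evaluation outside the calibrated span is an error, not a clamp", {
  no <- bundled_stiffness("NO")
  expect_error(forward_delta_f(no, 3.5), "extrapolation")
  expect_error(forward_delta_f(no, -3.01), "extrapolation")
  asym <- piecewise_stiffness("INT", c(100, 100, 100), symmetric = FALSE)
  expect_error(pathway_force(asym, -1), "symmetric")
  expect_equal(pathway_force(asym, 2), 0.2)
})

test_that("stiffness interpolation is exact at endpoints and linear in alpha", {
  no <- bundled_stiffness("NO")
  ti <- bundled_stiffness("TI")
  expect_equal(segment_stiffness(interpolate_stiffness(no, ti, 0)),
               segment_stiffness(no))
  expect_equal(segment_stiffness(interpolate_stiffness(no, ti, 1)),
               segment_stiffness(ti))
  mid <- interpolate_stiffness(no, ti, 0.5)
  expect_equal(mid$pathways$INT$k_mN_mm[1], (239.8 + 549.7) / 2)
  for (a in c(0.2, 1 / 3, 0.75)) {
    got <- segment_stiffness(interpolate_stiffness(no, ti, a))
    expect_equal(got,
                 (1 - a) * segment_stiffness(no) + a * segment_stiffness(ti))
  }
  expect_equal(interpolate_stiffness(no, ti, 0.25)$c, 0.9)
  expect_error(interpolate_stiffness(no, ti, 1.5), "alpha")
  other <- stiffness_set(
    piecewise_stiffness("INT", c(1, 2), breakpoints_mm = c(0, 1, 2)),
    piecewise_stiffness("NV1", c(1, 2), breakpoints_mm = c(0, 1, 2)),
    piecewise_stiffness("NV2", c(1, 2), breakpoints_mm = c(0, 1, 2)))
  expect_error(interpolate_stiffness(no, other, 0.5), "breakpoints")
})

test_that("position-to-knee-angle map anchors the reference at 90 degrees", {
  expect_equal(position_to_knee_angle(0), 90)
  expect_equal(position_to_knee_angle(c(-2, 1, 3), slope_deg_mm = 0),
               c(90, 90, 90))
  expect_equal(position_to_knee_angle(2, slope_deg_mm = 10,
                                      intercept_deg = 90), 110)
  expect_error(position_to_knee_angle(NaN), "finite")
})

test_that("protocol and stiffness constructors enforce their invariants", {
  expect_error(position_protocol(c(-1, 1, 0)), "increasing")
  expect_error(position_protocol(c(-1, 1)), "reference")
  expect_error(position_protocol(c(-1, 0, 0.0, 1)), "increasing")
  p <- position_protocol(-3:3)
  expect_equal(p$positions_mm[p$reference_index], 0)

  expect_error(piecewise_stiffness("INT", c(1, 2, 3)), NA)
  expect_error(piecewise_stiffness("INT", c(1, 2, 3),
                                   breakpoints_mm = c(0, 1, 2)),
               "one stiffness value per segment")
  expect_error(piecewise_stiffness("INT", c(1, 2),
                                   breakpoints_mm = c(1, 2, 3)),
               "start at 0")
  expect_error(piecewise_stiffness("INT", c(1, NA, 3)), "finite")
  no <- bundled_stiffness("NO")
  expect_error(stiffness_set(no$pathways$INT, no$pathways$NV1,
                             no$pathways$NV2, c = 1.2), "\\(0, 1\\]")
})
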