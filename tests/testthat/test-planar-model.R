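test_that("noiseless spiral traces are recovered exactly", {
  tr <- simulate_spiral_trace(10, 5, "archimedean", sigma_nm = 0)
  fit <- fit_spiral(tr, "archimedean")
  expect_equal(fit$a_nm, 10, tolerance = 1e-6)
  expect_equal(fit$b, 5, tolerance = 1e-6)
  expect_lt(fit$rms_residual_nm, 1e-9)
  expect_equal(unname(fit$center_nm), c(0, 0), tolerance = 1e-6)

  tre <- simulate_spiral_trace(8, 0.15, "exponential", sigma_nm = 0)
  fite <- fit_spiral(tre, "exponential")
  expect_equal(fite$a_nm, 8, tolerance = 1e-6)
  expect_equal(fite$b, 0.15, tolerance = 1e-6)
})

test_that("short or disordered traces raise typed errors", {
  short <- simulate_spiral_trace(10, 5, "archimedean", turns = 1.0,
                                 sigma_nm = 0)
  expect_error(fit_spiral(short), class = "vippgeom_insufficient_arc")
  expect_error(fit_spiral(short[1:10, ]),
               class = "vippgeom_invalid_argument")
  scrambled <- simulate_spiral_trace(10, 5, "archimedean", sigma_nm = 0)
  scrambled <- scrambled[c(seq(1, 80, 2), seq(80, 2, -2)), ]
  expect_error(fit_spiral(scrambled), class = "vippgeom_trace_error")
})

test_that("exponential growth parameter is recovered within 10% RMSE", {
  n_rep <- 100
  bs <- vapply(seq_len(n_rep), function(s) {
    tr <- simulate_spiral_trace(8, 0.15, "exponential", sigma_nm = 0.5,
                                seed = 1000 + s)
    fit_spiral(tr, "exponential")$b
  }, numeric(1))
  expect_lt(abs(mean(bs) - 0.15) / 0.15, 0.02)       # bias < 2%
  expect_lt(sqrt(mean((bs - 0.15)^2)) / 0.15, 0.10)  # RMSE < 10%

  bs_a <- vapply(seq_len(n_rep), function(s) {
    tr <- simulate_spiral_trace(10, 5, "archimedean", sigma_nm = 0.5,
                                seed = 2000 + s)
    fit_spiral(tr, "archimedean")$b
  }, numeric(1))
  expect_lt(abs(mean(bs_a) - 5) / 5, 0.02)
  expect_lt(sqrt(mean((bs_a - 5)^2)) / 5, 0.10)
})

test_that("AIC model selection is at least 95% correct on noisy traces", {
  n_each <- 100
  correct <- 0L
  for (s in seq_len(n_each)) {
    tr <- simulate_spiral_trace(10, 5, "archimedean", sigma_nm = 0.5,
                                seed = 3000 + s)
    if (fit_spiral(tr, "auto")$model == "archimedean") correct <- correct + 1L
    tre <- simulate_spiral_trace(8, 0.15, "exponential", sigma_nm = 0.5,
                                 seed = 4000 + s)
    if (fit_spiral(tre, "auto")$model == "exponential") correct <- correct + 1L
  }
  expect_gte(correct / (2 * n_each), 0.95)
})

test_that("tidy and glance expose the fitted spiral parameters", {
  fit <- fit_spiral(simulate_spiral_trace(10, 5, "archimedean",
                                          sigma_nm = 0))
  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "b"], 5, tolerance = 1e-6)
  gl <- generics::glance(fit)
  expect_equal(gl$model, "archimedean")
  expect_equal(gl$n_points, 80L)
})

test_that("ridge spacing across a bend matches the rigid-element model", {
  s <- spacing_across_bend(c(Inf, 516.857, 278.308))
  expect_equal(s$s_inner_A[1], 54)
  expect_equal(s$s_outer_A[1], 54)
  expect_equal(s$s_outer_A[2], 61, tolerance = 1e-3)
  expect_equal(s$s_inner_A[3], 41, tolerance = 1e-3)
  expect_error(spacing_across_bend(50),
               class = "vippgeom_invalid_argument")
  # ordering invariant and convergence to s0
  radii <- c(80, 150, 400, 1e4, 1e7)
  sb <- spacing_across_bend(radii)
  expect_true(all(sb$s_inner_A < 54 & 54 < sb$s_outer_A))
  expect_equal(sb$s_inner_A[5], 54, tolerance = 1e-4)
})

test_that("minimum planar diameter agrees between closed form and scan", {
  d_cf <- min_planar_diameter()
  d_scan <- min_planar_diameter(method = "scan")
  expect_equal(d_cf, 103.37, tolerance = 1e-3)
  expect_equal(d_scan, d_cf, tolerance = 1e-3) # 0.1% agreement
  # zero width bends freely
  expect_equal(min_planar_diameter(curvature_model(width_A = 1e-9)), 0,
               tolerance = 1e-9)
  # symmetric bounds make both constraints coincide
  m_sym <- curvature_model(s0_A = 54, s_min_A = 47, s_max_A = 61)
  r_out <- 54 * 67 / (61 - 54)
  expect_equal(min_planar_diameter(m_sym), 2 * r_out / 10)
})

test_that("minimum planar diameter is monotone in width and stretch slack", {
  widths <- c(60, 100, 134, 180)
  d_w <- vapply(widths, function(w)
    min_planar_diameter(curvature_model(width_A = w)), numeric(1))
  expect_true(all(diff(d_w) > 0))
  smaxes <- c(58, 61, 70, 90)
  d_s <- vapply(smaxes, function(s)
    min_planar_diameter(curvature_model(s_max_A = s, s_min_A = 20)),
    numeric(1))
  expect_true(all(diff(d_s) < 0))
})

test_that("observed ring diameters below the planar limit require tilt", {
  expect_true(requires_tilt(37.0))   # central rings in spirals
  expect_false(requires_tilt(200))
  expect_false(requires_tilt(min_planar_diameter())) # boundary feasible
})

test_that("ring geometry closes the circumference relation", {
  g17 <- ring_geometry(17, diameter_A = 340)
  expect_equal(g17$subunit_arc_A, pi * 340 / 17)
  expect_equal(g17$subunit_arc_A, 62.8, tolerance = 1e-2)
  g11 <- ring_geometry(11, diameter_A = 240)
  expect_equal(g11$subunit_arc_A, 68.5, tolerance = 1e-2)
  # spacing at the central-rung radius falls in the observed 53-59 range
  s <- ring_subunit_spacing(17, 146)
  expect_equal(s, 53.96, tolerance = 1e-2)
  expect_true(s > 53 && s < 59)
  # round trip diameter -> arc -> diameter
  g <- ring_geometry(14, diameter_A = 300)
  g2 <- ring_geometry(14, subunit_arc_A = g$subunit_arc_A)
  expect_equal(g2$diameter_A, 300)
  expect_error(ring_geometry(14), class = "vippgeom_invalid_argument")
  expect_error(ring_geometry(14, diameter_A = 300, subunit_arc_A = 60),
               class = "vippgeom_invalid_argument")
})

test_that("protofilament counts follow the width over spacing ratio", {
  expect_identical(protofilament_count(122, 32.5), 4L)
  expect_identical(protofilament_count(134, 32.5), 4L)
  expect_identical(protofilament_count(65, 32.5), 2L)
  expect_identical(protofilament_count(10, 32.5), 1L)
})

test_that("sensitivity report spans the stated bound uncertainty", {
  sens <- min_planar_diameter_sensitivity(delta_A = 2, step_A = 2)
  expect_equal(nrow(sens), 9L)
  expect_true(all(sens$min_planar_diameter_nm > 0))
  # looser stretch bound always shrinks the limit
  tight <- sens$min_planar_diameter_nm[sens$s_max_A == 59]
  loose <- sens$min_planar_diameter_nm[sens$s_max_A == 63]
  expect_true(all(tight >= loose))
})
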