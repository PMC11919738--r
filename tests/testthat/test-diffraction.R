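test_that("layer-line heights follow the helical selection rule", {
  sym <- helical_symmetry(2.159, 85.495)
  ll <- layer_lines(sym, n_range = c(-4, 0, 17), m_range = -4:4,
                    z_max_invA = 0.6) # keep the 1/rise line in range

  z4 <- ll$Z_invA[ll$n == -4 & ll$m == 1]
  expect_equal(z4, (-4 * 85.495 / 360 + 1) / 2.159, tolerance = 1e-12)
  expect_equal(1 / z4, 43.13, tolerance = 1e-2)
  z17 <- ll$Z_invA[ll$n == 17 & ll$m == -4]
  expect_equal(1 / z17, 57.93, tolerance = 1e-2)
  # the (0, 1) line sits at 1/rise
  z0 <- ll$Z_invA[ll$n == 0 & ll$m == 1]
  expect_equal(z0, 1 / 2.159)
  expect_true(all(diff(ll$Z_invA) >= 0))
  # selection-rule invariant: Z * rise - n * twist / 360 is an integer
  resid <- ll$Z_invA * 2.159 - ll$n * 85.495 / 360
  expect_equal(resid, round(resid), tolerance = 1e-9)
})

test_that("layer lines are dual to start families (1/Z = axial spacing)", {
  syms <- random_symmetries(200, seed = 61)
  for (i in seq_len(nrow(syms))) {
    sym <- helical_symmetry(syms$rise_A[i], syms$twist_deg[i])
    fam <- start_family(sym, 1:25)
    for (k in c(1, 2, 5, 12, 25)) {
      step <- fam$step_deg[k]
      if (step == 0) next
      # k * twist = step + 360 * t; the line (n = k, m = -t) then sits at
      # Z = step / (360 * rise), whose reciprocal is the axial spacing
      t <- round((k * sym$twist_deg - step) / 360)
      z <- (k * sym$twist_deg / 360 - t) / sym$rise_A
      expect_equal(1 / abs(z), fam$axial_spacing_A[k], tolerance = 1e-9)
    }
  }
})

test_that("symmetry candidates round-trip generated reflections", {
  sym <- helical_symmetry(2.159, 85.495)
  refl <- tibble::tibble(
    Z_invA = c((-4 * 85.495 / 360 + 1) / 2.159,
               (17 * 85.495 / 360 - 4) / 2.159),
    n = c(-4L, 17L)
  )
  cand <- symmetry_candidates(refl)
  expect_equal(cand$rise_A[1], 2.159, tolerance = 1e-9)
  expect_equal(cand$twist_deg[1], 85.495, tolerance = 1e-9)
  expect_lt(cand$residual_invA[1], 1e-9)

  sym2 <- helical_symmetry(2.372, -75.860)
  refl2 <- tibble::tibble(
    Z_invA = c((-5 * -75.860 / 360 + 1) / 2.372,
               (14 * -75.860 / 360 + 3) / 2.372),
    n = c(-5L, 14L)
  )
  cand2 <- symmetry_candidates(refl2)
  hit <- abs(cand2$rise_A - 2.372) < 0.005 &
    abs(cand2$twist_deg - -75.860) < 0.01
  expect_true(any(hit))

  expect_error(symmetry_candidates(refl[1, ]),
               class = "vippgeom_invalid_argument")
})

test_that("candidate search recovers random truths across the m grid", {
  syms <- random_symmetries(200, seed = 71)
  syms$rise_A <- 1 + (syms$rise_A - 1) * 9 / 9 # already in [1, 10]
  ok <- 0L
  for (i in seq_len(nrow(syms))) {
    rise <- syms$rise_A[i]; twist <- syms$twist_deg[i]
    if (abs(twist) < 1) next # near-degenerate indexing, excluded by bounds
    z1 <- (-2 * twist / 360 + 1) / rise
    z2 <- (5 * twist / 360 + 2) / rise
    refl <- tibble::tibble(Z_invA = c(z1, z2), n = c(-2L, 5L))
    cand <- symmetry_candidates(refl, m_range = -6:6)
    hit <- abs(cand$rise_A - rise) < 0.005 &
      abs(cand$twist_deg - twist) < 0.01
    expect_true(any(hit))
    ok <- ok + 1L
  }
  expect_gt(ok, 150L)
})

test_that("simulated power spectra peak on predicted layer lines", {
  sym <- helical_symmetry(2.159, 85.495)
  sp <- simulate_power_spectrum(sym, 92.75, image_size_px = 512,
                                pixel_A = 1.1, seed = 1)
  prof <- layer_line_profile(sp)
  fourier_px <- 1 / (512 * 1.1)
  for (z_true in c(0.02319, 0.01726)) {
    # the local maximum within +/- 2 pixels of the predicted height sits
    # within one Fourier pixel of it (a wider window would catch the
    # leakage skirt of the neighbouring stronger line)
    win <- which(abs(prof$Z_invA - z_true) <= 2 * fourier_px)
    z_pk <- prof$Z_invA[win][which.max(prof$amplitude[win])]
    expect_lt(abs(z_pk - z_true), 1.05 * fourier_px)
  }
  # determinism
  sp2 <- simulate_power_spectrum(sym, 92.75, image_size_px = 512,
                                 pixel_A = 1.1, seed = 1)
  expect_identical(sp$amplitude, sp2$amplitude)
})

test_that("a featureless cylinder yields no off-equator peaks", {
  sym <- helical_symmetry(2.159, 85.495)
  # heavy blur approximates the uniform-cylinder limit
  sp <- simulate_power_spectrum(sym, 92.75, image_size_px = 256,
                                pixel_A = 1.1, sigma_A = 60, seed = 2)
  prof <- layer_line_profile(sp)
  off <- prof$Z_invA > 0.01
  eq <- abs(prof$Z_invA) < 0.004
  # off-equator layer lines vanish relative to the equator...
  expect_lt(max(prof$amplitude[off]), 0.05 * max(prof$amplitude[eq]))
  # ...whereas the resolved lattice at the same geometry keeps them
  sps <- simulate_power_spectrum(sym, 92.75, image_size_px = 256,
                                 pixel_A = 1.1, sigma_A = 8, seed = 2)
  profs <- layer_line_profile(sps)
  offs <- profs$Z_invA > 0.01
  eqs <- abs(profs$Z_invA) < 0.004
  expect_gt(max(profs$amplitude[offs]), 0.3 * max(profs$amplitude[eqs]))
})
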