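test_that("angle reduction maps onto (-180, 180] and preserves congruence", {
  expect_equal(reduce_angle(341.98), -18.02)
  expect_equal(reduce_angle(85.495), 85.495)
  expect_equal(reduce_angle(360), 0)
  expect_equal(reduce_angle(180), 180)
  expect_equal(reduce_angle(-180), 180)
  angles <- withr::with_seed(11, stats::runif(200, -2000, 2000))
  red <- reduce_angle(angles)
  expect_true(all(red > -180 & red <= 180))
  expect_true(all(abs((angles - red) %% 360) < 1e-9 |
                    abs((angles - red) %% 360 - 360) < 1e-9))
  expect_error(reduce_angle(Inf), class = "vippgeom_invalid_argument")
})

test_that("helical symmetry validates its invariants", {
  expect_error(helical_symmetry(0, 85), class = "vippgeom_invalid_argument")
  expect_error(helical_symmetry(2, 360), class = "vippgeom_invalid_argument")
  expect_error(helical_symmetry(2, 85, r_lumen_A = 100, r_outer_A = 50),
               class = "vippgeom_invalid_argument")
  sym <- helical_symmetry(2, 725) # reduced on construction
  expect_equal(sym$twist_deg, 5)
})

test_that("start families carry the paper lattices' steps and handedness", {
  sym <- sym_da6_l3()
  fam <- start_family(sym, c(4, 17, 21))
  expect_equal(fam$step_deg, c(-18.02, 13.415, -4.605), tolerance = 1e-9)
  expect_equal(fam$handedness, c("left", "right", "left"))
  # 4-start axial inter-strand spacing from the refined parameters
  expect_equal(fam$axial_spacing_A[1], 360 * 2.159 / 18.02,
               tolerance = 1e-12)
  expect_equal(fam$axial_spacing_A[1], 43.13, tolerance = 1e-3)
  # trivial case: rise 10, twist 90, k = 1
  f1 <- start_family(helical_symmetry(10, 90), 1)
  expect_equal(f1$step_deg, 90)
  expect_equal(f1$axial_spacing_A, 40)
  expect_error(start_family(sym, 0), class = "vippgeom_invalid_argument")
})

test_that("axial spacing identity holds over random symmetries", {
  syms <- random_symmetries(200, seed = 21)
  for (i in seq_len(nrow(syms))) {
    sym <- helical_symmetry(syms$rise_A[i], syms$twist_deg[i])
    fam <- start_family(sym, 1:25)
    nz <- fam$step_deg != 0
    expect_equal(fam$axial_spacing_A[nz] * abs(fam$step_deg[nz]),
                 rep(360 * sym$rise_A, sum(nz)), tolerance = 1e-9)
    expect_equal(fam$strand_pitch_A[nz],
                 fam$k[nz] * fam$axial_spacing_A[nz], tolerance = 1e-9)
  }
})

test_that("a zero-step family is axial with infinite spacing, not an error", {
  fam <- start_family(helical_symmetry(3, 90), 4)
  expect_equal(fam$handedness, "axial")
  expect_equal(fam$axial_spacing_A, Inf)
})

test_that("near-axial family reproduces the observed start counts", {
  expect_identical(near_axial_family(helical_symmetry(2.159, 85.495)), 21L)
  expect_identical(near_axial_family(helical_symmetry(2.155, 68.507)), 21L)
  expect_identical(near_axial_family(helical_symmetry(2.372, -75.860)), 19L)
  # exact zero step wins
  expect_identical(near_axial_family(helical_symmetry(5, 90), k_max = 8), 4L)
})

test_that("near-axial start count is invariant under twist sign flip", {
  syms <- random_symmetries(100, seed = 31)
  for (i in seq_len(nrow(syms))) {
    a <- helical_symmetry(syms$rise_A[i], syms$twist_deg[i])
    b <- helical_symmetry(syms$rise_A[i], -syms$twist_deg[i])
    expect_identical(near_axial_family(a), near_axial_family(b))
  }
})

test_that("lattice vectors decompose into circumferential and axial parts", {
  sym <- sym_da6_l3()
  v <- lattice_vector(sym, c(17, 21), 92.75)
  expect_equal(v$length_A[1], oracle_vector_length(2.159, 85.495, 17, 92.75))
  expect_equal(v$length_A[1], 42.65, tolerance = 1e-3)
  expect_equal(abs(v$dx_A[2]), 7.455, tolerance = 1e-2)
  expect_equal(v$dz_A[2], 45.339, tolerance = 1e-9)
  expect_equal(v$length_A^2, v$dx_A^2 + v$dz_A^2, tolerance = 1e-9)
  # radius 0 leaves the axial component only
  v0 <- lattice_vector(sym, 17, 0)
  expect_equal(v0$length_A, 17 * 2.159)
  expect_error(lattice_vector(sym, 4, -1),
               class = "vippgeom_invalid_argument")
})

test_that("principal vectors match the indexed Bessel pairs at mid-wall", {
  sym3 <- sym_da6_l3()
  pv <- principal_vectors(sym3, mid_wall_radius(sym3))
  expect_identical(pv$k, c(4L, 17L))
  expect_identical(pv$handedness, c("left", "right"))
  symK <- helical_symmetry(2.440, -75.835, r_lumen_A = 52.5, r_outer_A = 105)
  pvK <- principal_vectors(symK, mid_wall_radius(symK))
  expect_identical(pvK$k, c(5L, 14L))
  pvT <- principal_vectors(helical_symmetry(10, 120), 10, k_max = 5)
  expect_identical(pvT$k, oracle_principal(10, 120, 10, 5))
})

test_that("principal vectors agree with brute force over random symmetries", {
  syms <- random_symmetries(1000, seed = 41)
  radii <- withr::with_seed(42, stats::runif(1000, 20, 150))
  for (i in seq_len(nrow(syms))) {
    pv <- principal_vectors(helical_symmetry(syms$rise_A[i],
                                             syms$twist_deg[i]),
                            radii[i], k_max = 25)
    expect_identical(pv$k,
                     oracle_principal(syms$rise_A[i], syms$twist_deg[i],
                                      radii[i], 25))
  }
})

test_that("subunit spacing grows monotonically with radius", {
  syms <- random_symmetries(50, seed = 51)
  radii <- seq(0, 150, by = 10)
  for (i in seq_len(nrow(syms))) {
    sym <- helical_symmetry(syms$rise_A[i], syms$twist_deg[i])
    for (k in c(1, 4, 17)) {
      sp <- vapply(radii, function(r) subunit_spacing_at_radius(sym, k, r),
                   numeric(1))
      expect_true(all(diff(sp) >= -1e-12))
    }
  }
  expect_equal(subunit_spacing_at_radius(sym_da6_l3(), 4, 92.75), 30.42,
               tolerance = 1e-3)
})

test_that("start-family table flags near-axial and principal families", {
  tab <- start_family_table(sym_da6_l3())
  expect_identical(tab$k[tab$near_axial], 21L)
  expect_identical(sort(tab$k[tab$principal]), c(4L, 17L))
  expect_equal(nrow(tab), 25L)
})
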