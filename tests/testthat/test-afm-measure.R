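test_that("ridge period is exact on a pure noiseless sinusoid", {
  px <- 0.7
  n <- 256
  g <- (seq_len(n) - 0.5) * px
  for (period_nm in c(5.4, 7.7)) {
    h <- outer(g, g, function(y, x) 5 + 0.3 * sin(2 * pi * x / period_nm))
    img <- afm_image(h, px)
    expect_equal(ridge_period(img), period_nm * 10, tolerance = 0.005)
  }
  # rotated pattern
  h <- outer(g, g, function(y, x)
    5 + 0.3 * sin(2 * pi * (x * cos(0.5) + y * sin(0.5)) / 5.4))
  expect_equal(ridge_period(afm_image(h, px)), 54, tolerance = 0.5)
})

test_that("ridge period recovers the sheet's 54 A ridges within 2%", {
  sh <- synth_sheet(field_nm = 700, pixel_nm = 0.7, seed = 42)
  rp <- ridge_period(sh$image)
  expect_equal(rp, 54, tolerance = 0.02)
})

test_that("white noise yields a no-periodicity signal, not an error", {
  img <- afm_image(withr::with_seed(3, matrix(stats::rnorm(256^2, 0, 0.1),
                                              256)), 0.7)
  r <- ridge_period(img)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "noise floor")
})

test_that("detection classifies a field of spirals with their rings", {
  sf <- synth_spiral_field(n_spirals = 40, seed = 1)
  det <- detect_objects(sf$image)
  expect_equal(nrow(det), 40L)
  expect_gte(mean(det$kind == "spiral"), 0.95)
  # rings recorded in truth are found as central rings
  expect_equal(sum(det$has_central_ring), sum(sf$truth$has_ring))
})

test_that("detection handles single objects and blank fields", {
  one <- synth_ring_field(n_rings = 1, field_nm = 100, pixel_nm = 1,
                          diameter_mean_nm = 40, diameter_sd_nm = 0,
                          noise_sd_nm = 0, seed = 5)
  det <- detect_objects(one$image)
  expect_equal(nrow(det), 1L)
  expect_equal(det$kind, "ring")
  blank <- afm_image(withr::with_seed(4, matrix(stats::rnorm(200^2, 0, 0.1),
                                                200)), 1)
  expect_equal(nrow(detect_objects(blank)), 0L)
})

test_that("sheets are classified by size and solidity", {
  sh <- synth_sheet(field_nm = 300, pixel_nm = 0.7, seed = 42)
  det <- detect_objects(sh$image)
  expect_true("sheet" %in% det$kind)
})

test_that("morphometrics recover generator truth", {
  sf <- synth_spiral_field(n_spirals = 40, seed = 1)
  rep <- object_morphometrics(detect_objects(sf$image))
  # match measured objects to truth by centre
  idx <- vapply(seq_len(nrow(sf$truth)), function(i) {
    which.min((rep$cx_nm - sf$truth$cx_nm[i])^2 +
                (rep$cy_nm - sf$truth$cy_nm[i])^2)
  }, integer(1))
  err <- rep$diameter_nm[idx] - sf$truth$diameter_nm
  expect_lt(max(abs(err)), 2 * sf$image$pixel_nm + 1)
  sem <- stats::sd(sf$truth$diameter_nm) / sqrt(nrow(sf$truth))
  expect_lt(abs(mean(rep$diameter_nm[idx]) -
                  mean(sf$truth$diameter_nm)), 2 * sem)
  # height offset of the plateau
  expect_equal(mean(rep$height_offset_nm), 5.5, tolerance = 0.1)
  # area equals the rendered footprint
  expect_equal(rep$area_nm2, rep$n_px * sf$image$pixel_nm^2)
})

test_that("filament widths are recovered within 5%", {
  ff <- synth_filament_field(n_filaments = 13, seed = 2)
  rep <- object_morphometrics(detect_objects(ff$image))
  expect_true(all(rep$kind == "filament"))
  expect_lt(abs(mean(rep$width_nm) - mean(ff$truth$width_nm)) /
              mean(ff$truth$width_nm), 0.05)
  # sheet height offset recovery
  sh <- synth_sheet(field_nm = 300, pixel_nm = 0.7, seed = 42)
  srep <- object_morphometrics(detect_objects(sh$image))
  sheet_row <- srep$kind == "sheet"
  expect_equal(srep$height_offset_nm[sheet_row][1], 5.5, tolerance = 0.1)
})

test_that("measurements are invariant to translation and rotation", {
  sf <- synth_spiral_field(n_spirals = 1, field_nm = 200, pixel_nm = 1.5,
                           diameter_mean_nm = 70, diameter_sd_nm = 0,
                           ring_fraction = 0, noise_sd_nm = 0, seed = 6)
  h <- sf$image$heights
  base <- object_morphometrics(detect_objects(afm_image(h, 1.5)))
  rot <- object_morphometrics(detect_objects(
    afm_image(t(h[nrow(h):1, ]), 1.5)))  # 90-degree rotation
  shift <- rbind(matrix(0, 8, ncol(h)), h[1:(nrow(h) - 8), ])
  tra <- object_morphometrics(detect_objects(afm_image(shift, 1.5)))
  expect_equal(rot$diameter_nm, base$diameter_nm, tolerance = 1e-6)
  expect_equal(tra$diameter_nm, base$diameter_nm, tolerance = 1e-6)
  expect_equal(rot$width_nm, base$width_nm, tolerance = 1e-6)
  expect_equal(rot$kind, base$kind)
})

test_that("growth velocities are recovered per interval", {
  gs <- synth_growth_series(n_frames = 6, n_filaments = 5, seed = 7)
  gr <- growth_rate(gs)
  expect_equal(nrow(gr), 5L * 5L)
  expect_true(!any(gr$flagged))
  meas <- gr |>
    dplyr::group_by(track) |>
    dplyr::summarise(v = mean(velocity_nm_s))
  # match tracks to truth by recovered velocity ordering
  expect_equal(sort(meas$v), sort(gs$truth$velocity_nm_s), tolerance = 0.15)
  expect_lt(abs(mean(gr$velocity_nm_s) - mean(gs$truth$velocity_nm_s)) /
              max(mean(gs$truth$velocity_nm_s), 1), 0.15)
})

test_that("degenerate growth inputs behave as specified", {
  gz <- synth_growth_series(n_frames = 3, n_filaments = 3,
                            velocity_mean_nm_s = 0, velocity_sd_nm_s = 0,
                            noise_sd_nm = 0, seed = 8)
  gr <- growth_rate(gz)
  expect_equal(gr$velocity_nm_s, rep(0, nrow(gr)), tolerance = 1e-9)
  expect_error(growth_rate(gz$frames[1:2], dt_s = 1),
               class = "vippgeom_invalid_argument")
})

test_that("ring protrusion is measured against the surrounding spiral", {
  sf <- synth_spiral_field(n_spirals = 6, ring_fraction = 1,
                           diameter_mean_nm = 100, diameter_sd_nm = 10,
                           noise_sd_nm = 0.05, seed = 10)
  det <- detect_objects(sf$image)
  ids <- det$object_id[det$has_central_ring]
  expect_gte(length(ids), 5L)
  pr <- vapply(ids, function(id) ring_protrusion(det, id), numeric(1))
  expect_equal(mean(pr), 1.0, tolerance = 0.1)
  # spiral without a ring gives a not-applicable signal
  sf0 <- synth_spiral_field(n_spirals = 1, field_nm = 200, pixel_nm = 1.5,
                            diameter_mean_nm = 80, diameter_sd_nm = 0,
                            ring_fraction = 0, seed = 11)
  det0 <- detect_objects(sf0$image)
  r <- ring_protrusion(det0, det0$object_id[1])
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "no central ring")
})

test_that("summaries aggregate per object class", {
  sf <- synth_spiral_field(n_spirals = 10, seed = 1)
  s <- summarize_measurements(object_morphometrics(detect_objects(sf$image)))
  expect_true("spiral" %in% s$kind)
  expect_equal(sum(s$n), 10L)
  expect_true(all(s$diameter_sd_nm >= 0, na.rm = TRUE))
})
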