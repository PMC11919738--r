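#' @section Synthetic AFM presets:
#' The generators emulate the measured statistics of membrane-bound Vipp1
#' assemblies: sheet plateaus 5.5 nm above the membrane carrying 54 Å
#' surface ridges and fainter orthogonal 122 Å seams; spiral filaments of
#' width 13.4 +/- 0.9 nm whose outer diameters follow the observed
#' 82.7 +/- 37.8 nm law; central rings protruding 1.0 +/- 0.2 nm above the
#' spiral plateau; standalone rings (35.5 +/- 2.9 nm across, 9.6 +/- 2.2 nm
#' high); and filaments elongating at 24 +/- 19.6 nm/s. Truth tables record
#' every rendered object. Tip convolution and scanner drift are not
#' simulated.
#' @name afm-synth
NULL

# Moment-matched truncated normal: the reported statistics are sample
# mean/SD of physically bounded measurements, so the generator solves for
# the underlying normal whose lower-truncated law has exactly the configured
# mean and SD, then samples by inversion.
truncnorm_params <- function(mean, sd, lower) {
  if (!is.finite(lower) || pnorm((lower - mean) / sd) < 1e-6) {
    return(c(mu = mean, sigma = sd))
  }
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    a <- (lower - mu) / sigma
    lam <- dnorm(a) / (1 - pnorm(a))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    (m - mean)^2 + (sqrt(max(v, 1e-12)) - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, control = list(reltol = 1e-14,
                                                     maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm_matched <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) return(rep(mean, n))
  p <- truncnorm_params(mean, sd, lower)
  a <- if (is.finite(lower)) pnorm(lower, p["mu"], p["sigma"]) else 0
  stats::qnorm(a + runif(n) * (1 - a), p["mu"], p["sigma"])
}

blank_canvas <- function(field_nm, pixel_nm) {
  n <- max(16L, round(field_nm / pixel_nm))
  matrix(0, n, n)
}

add_noise <- function(heights, noise_sd_nm, seed) {
  if (noise_sd_nm <= 0) return(heights)
  with_seed(class_seed(seed, "noise"), {
    heights + matrix(rnorm(length(heights), 0, noise_sd_nm),
                     nrow(heights))
  })
}

# pixel-centre coordinate grids in nm
grid_nm <- function(heights, pixel_nm) {
  list(x = (seq_len(ncol(heights)) - 0.5) * pixel_nm,
       y = (seq_len(nrow(heights)) - 0.5) * pixel_nm)
}

# raise pixels within `radius` of the polyline samples (cx, cy) to `height`;
# per-sample local windows keep the cost proportional to the curve length
stamp_polyline <- function(heights, pixel_nm, cx, cy, radius, height) {
  nr <- nrow(heights); nc <- ncol(heights)
  half <- ceiling(radius / pixel_nm) + 1L
  for (s in seq_along(cx)) {
    ic <- round(cx[s] / pixel_nm + 0.5)
    ir <- round(cy[s] / pixel_nm + 0.5)
    rows <- max(1L, ir - half):min(nr, ir + half)
    cols <- max(1L, ic - half):min(nc, ic + half)
    if (!length(rows) || !length(cols)) next
    d2 <- outer(((rows - 0.5) * pixel_nm - cy[s])^2,
                ((cols - 0.5) * pixel_nm - cx[s])^2, `+`)
    sub <- heights[rows, cols]
    hit <- d2 <= radius^2 & sub < height
    if (any(hit)) {
      sub[hit] <- height
      heights[rows, cols] <- sub
    }
  }
  heights
}

# raise pixels within `radius` of the segment (x0,y0)-(x1,y1) to `height`
# (exact capsule footprint, fully vectorized over the segment bbox)
stamp_segment <- function(heights, pixel_nm, x0, y0, x1, y1, radius,
                          height) {
  lo_x <- max(1L, floor((min(x0, x1) - radius) / pixel_nm))
  hi_x <- min(ncol(heights), ceiling((max(x0, x1) + radius) / pixel_nm) + 1L)
  lo_y <- max(1L, floor((min(y0, y1) - radius) / pixel_nm))
  hi_y <- min(nrow(heights), ceiling((max(y0, y1) + radius) / pixel_nm) + 1L)
  if (lo_x > hi_x || lo_y > hi_y) return(heights)
  gx <- (lo_x:hi_x - 0.5) * pixel_nm
  gy <- (lo_y:hi_y - 0.5) * pixel_nm
  ux <- x1 - x0; uy <- y1 - y0
  L2 <- ux^2 + uy^2
  px <- matrix(rep(gx, each = length(gy)), length(gy))
  py <- matrix(rep(gy, length(gx)), length(gy))
  t <- if (L2 > 0) pmin(pmax(((px - x0) * ux + (py - y0) * uy) / L2, 0), 1)
       else 0
  d2 <- (px - (x0 + t * ux))^2 + (py - (y0 + t * uy))^2
  sub <- heights[lo_y:hi_y, lo_x:hi_x]
  hit <- d2 <= radius^2
  sub[hit] <- pmax(sub[hit], height)
  heights[lo_y:hi_y, lo_x:hi_x] <- sub
  heights
}

stamp_annulus <- function(heights, pixel_nm, cx, cy, r_outer, r_inner,
                          height) {
  lo_x <- max(1L, floor((cx - r_outer) / pixel_nm))
  hi_x <- min(ncol(heights), ceiling((cx + r_outer) / pixel_nm) + 1L)
  lo_y <- max(1L, floor((cy - r_outer) / pixel_nm))
  hi_y <- min(nrow(heights), ceiling((cy + r_outer) / pixel_nm) + 1L)
  gx <- (lo_x:hi_x - 0.5) * pixel_nm
  gy <- (lo_y:hi_y - 0.5) * pixel_nm
  d2 <- outer((gy - cy)^2, (gx - cx)^2, `+`)
  hit <- d2 <= r_outer^2 & d2 >= r_inner^2
  sub <- heights[lo_y:hi_y, lo_x:hi_x]
  sub[hit] <- pmax(sub[hit], height)
  heights[lo_y:hi_y, lo_x:hi_x] <- sub
  heights
}

# non-overlapping centre placement by rejection sampling
place_centers <- function(n, field_nm, radii_nm, margin_nm = 8,
                          max_attempts = 1e4) {
  cx <- numeric(0); cy <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- runif(1, radii_nm[i] + margin_nm, field_nm - radii_nm[i] - margin_nm)
      y <- runif(1, radii_nm[i] + margin_nm, field_nm - radii_nm[i] - margin_nm)
      if (!length(cx) ||
          all(sqrt((cx - x)^2 + (cy - y)^2) >=
                radii_nm[seq_along(cx)] + radii_nm[i] + margin_nm)) {
        cx <- c(cx, x); cy <- c(cy, y); placed <- TRUE; break
      }
    }
    if (!placed) {
      abort(sprintf("could not place object %d in %d attempts.", i,
                    max_attempts),
            class = "vippgeom_placement_error")
    }
  }
  tibble(cx_nm = cx, cy_nm = cy)
}

#' Synthetic AFM image of an ordered planar sheet
#'
#' Renders a membrane background at 0 nm and a central rectangular sheet
#' plateau at `height_nm`, modulated by a sinusoidal ridge pattern of the
#' stated period and amplitude plus a fainter orthogonal seam pattern, with
#' additive Gaussian height noise. Deterministic per seed (the ridge
#' direction is drawn from the seed unless fixed).
#'
#' @param field_nm Square field size (nm).
#' @param pixel_nm Pixel size (nm); must satisfy Nyquist for the ridges
#'   (`pixel_nm <= ridge_period_A / 20` since the period is in Å).
#' @param ridge_period_A Ridge period (Å; 54).
#' @param height_nm Sheet plateau height above the membrane (nm; 5.5).
#' @param seam_period_A Orthogonal seam period (Å; 122, the merged-filament
#'   seam repeat).
#' @param ridge_amplitude_nm,seam_amplitude_nm Modulation amplitudes (nm).
#' @param ridge_angle_deg Ridge normal direction; `NULL` draws it uniformly.
#' @param margin_frac Membrane margin around the sheet (fraction of field).
#' @param noise_sd_nm Gaussian height noise SD (nm).
#' @param seed Integer seed.
#' @return List with `image` ([afm_image()]) and `truth` (one-row tibble).
#' @examples
#' sh <- synth_sheet(field_nm = 250, pixel_nm = 0.7, seed = 42)
#' @export
synth_sheet <- function(field_nm = 1000, pixel_nm = 0.7,
                        ridge_period_A = 54, height_nm = 5.5,
                        seam_period_A = 122, ridge_amplitude_nm = 0.3,
                        seam_amplitude_nm = 0.15, ridge_angle_deg = NULL,
                        margin_frac = 0.15, noise_sd_nm = 0.1, seed = 42) {
  check_number(field_nm, "field_nm"); check_number(pixel_nm, "pixel_nm")
  if (pixel_nm > ridge_period_A / 10 / 2) {
    stop_invalid("pixel_nm violates Nyquist for the ridge period.")
  }
  if (is.null(ridge_angle_deg)) {
    ridge_angle_deg <- with_seed(class_seed(seed, "angle"),
                                 runif(1, 0, 180))
  }
  h <- blank_canvas(field_nm, pixel_nm)
  g <- grid_nm(h, pixel_nm)
  m0 <- margin_frac * field_nm
  in_sheet_x <- g$x >= m0 & g$x <= field_nm - m0
  in_sheet_y <- g$y >= m0 & g$y <= field_nm - m0
  phi <- deg2rad(ridge_angle_deg)
  u <- outer(g$y * sin(phi), g$x * cos(phi), `+`)   # along ridge normal
  v <- outer(g$y * cos(phi), -g$x * sin(phi), `+`)  # along ridges
  pat <- height_nm +
    ridge_amplitude_nm * sin(2 * pi * u / (ridge_period_A / 10)) +
    seam_amplitude_nm * sin(2 * pi * v / (seam_period_A / 10))
  mask <- outer(in_sheet_y, in_sheet_x, `&`)
  h[mask] <- pat[mask]
  h <- add_noise(h, noise_sd_nm, seed)
  img <- afm_image(h, pixel_nm,
                   metadata = list(seed = seed, preset = "sheet",
                                   noise_sd_nm = noise_sd_nm))
  truth <- tibble(object_id = 1L, kind = "sheet",
                  cx_nm = field_nm / 2, cy_nm = field_nm / 2,
                  diameter_nm = NA_real_, width_nm = NA_real_,
                  height_nm = height_nm, ridge_period_A = ridge_period_A,
                  seam_period_A = seam_period_A,
                  ridge_angle_deg = ridge_angle_deg)
  list(image = img, truth = truth)
}

#' Synthetic field of spiral filaments with optional central rings
#'
#' Renders non-overlapping Archimedean spiral filaments whose outer
#' diameters, widths and plateau heights follow the configured laws
#' (defaults are the measured statistics). The turn spacing is the filament
#' width plus a membrane gap, so neighbouring turns stay resolvable. A
#' fraction of spirals carries a central ring protruding above the spiral
#' plateau. Rejection sampling prevents overlaps; a placement error is
#' raised after 1e4 failed attempts. The truth table records every object.
#'
#' @param n_spirals Number of spirals.
#' @param field_nm Square field size (nm); `NULL` sizes the field for the
#'   requested count.
#' @param pixel_nm Pixel size (nm).
#' @param diameter_mean_nm,diameter_sd_nm,diameter_min_nm Outer-diameter
#'   law: moment-matched truncated normal (mean/SD are realized moments).
#' @param width_mean_nm,width_sd_nm Filament width law (nm).
#' @param height_nm Filament plateau height above the membrane (nm).
#' @param gap_nm Membrane gap between successive turns (nm).
#' @param ring_fraction Fraction of spirals given a central ring.
#' @param ring_diameter_mean_nm,ring_diameter_sd_nm Central-ring outer
#'   diameter law (nm); rings are shrunk when a small spiral cannot contain
#'   the drawn diameter.
#' @param ring_protrusion_nm Ring protrusion above the spiral plateau (nm).
#' @param noise_sd_nm Gaussian height noise SD (nm).
#' @param seed Integer seed.
#' @return List with `image` and `truth` (per-spiral rows: centre, outer
#'   `diameter_nm`, `width_nm`, `height_nm`, `has_ring`,
#'   `ring_diameter_nm`, `ring_protrusion_nm`, spiral model `b_nm_per_rad`,
#'   `turns`).
#' @export
synth_spiral_field <- function(n_spirals = 100, field_nm = NULL,
                               pixel_nm = 2,
                               diameter_mean_nm = 82.7,
                               diameter_sd_nm = 37.8,
                               diameter_min_nm = 30,
                               width_mean_nm = 13.4, width_sd_nm = 0.9,
                               height_nm = 5.5, gap_nm = 6,
                               ring_fraction = 0.3,
                               ring_diameter_mean_nm = 37,
                               ring_diameter_sd_nm = 3.9,
                               ring_protrusion_nm = 1.0,
                               noise_sd_nm = 0.1, seed = 1) {
  n_spirals <- check_count(n_spirals, "n_spirals")
  pars <- with_seed(class_seed(seed, "spiral"), {
    tibble(
      object_id = seq_len(n_spirals),
      diameter_nm = rtruncnorm_matched(n_spirals, diameter_mean_nm,
                                       diameter_sd_nm, diameter_min_nm),
      width_nm = rtruncnorm_matched(n_spirals, width_mean_nm, width_sd_nm,
                                    lower = 2),
      has_ring = runif(n_spirals) < ring_fraction,
      ring_diameter_nm = rtruncnorm_matched(n_spirals,
                                            ring_diameter_mean_nm,
                                            ring_diameter_sd_nm, lower = 14)
    )
  })
  if (is.null(field_nm)) {
    field_nm <- ceiling(sqrt(max(1, n_spirals)) *
                          (diameter_mean_nm + 2 * diameter_sd_nm + 40) /
                          0.55)
    field_nm <- max(field_nm, max(pars$diameter_nm) + 60)
  }
  pos <- with_seed(class_seed(seed, "placement"),
                   place_centers(n_spirals, field_nm,
                                 pars$diameter_nm / 2))
  pars <- dplyr::bind_cols(pars, pos)

  h <- blank_canvas(field_nm, pixel_nm)
  truth_rows <- list()
  for (i in seq_len(n_spirals)) {
    p <- pars[i, ]
    spacing <- p$width_nm + gap_nm
    b <- spacing / (2 * pi)
    r_max <- p$diameter_nm / 2 - p$width_nm / 2
    ring_d <- NA_real_
    r_min <- p$width_nm / 2 + 1
    if (p$has_ring) {
      ring_d <- min(p$ring_diameter_nm,
                    max(14, p$diameter_nm - 2 * (p$width_nm + gap_nm)))
      r_min <- max(r_min, ring_d / 2 - 2) # arm abuts the ring edge
    }
    if (r_max <= r_min) r_max <- r_min + 1
    th <- seq(r_min / b, r_max / b, by = (pixel_nm * 0.6) / r_max)
    r_arm <- b * th
    # the outermost turn of a mature spiral hugs the perimeter: continue at
    # constant radius for just over half a turn so the rendered outer
    # extent equals the nominal diameter in every direction
    th_arc <- seq(r_max / b, r_max / b + 1.2 * pi,
                  by = (pixel_nm * 0.6) / r_max)
    th <- c(th, th_arc)
    r_arm <- c(r_arm, rep(r_max, length(th_arc)))
    phase <- 2 * pi * (i %% 7) / 7
    cx <- p$cx_nm + r_arm * cos(th + phase)
    cy <- p$cy_nm + r_arm * sin(th + phase)
    h <- stamp_polyline(h, pixel_nm, cx, cy, p$width_nm / 2, height_nm)
    if (p$has_ring) {
      wall <- min(p$width_nm, ring_d / 2 - 2)
      h <- stamp_annulus(h, pixel_nm, p$cx_nm, p$cy_nm, ring_d / 2,
                         max(0, ring_d / 2 - wall),
                         height_nm + ring_protrusion_nm)
    }
    truth_rows[[i]] <- tibble(
      object_id = i, kind = "spiral", cx_nm = p$cx_nm, cy_nm = p$cy_nm,
      diameter_nm = p$diameter_nm, width_nm = p$width_nm,
      height_nm = height_nm, has_ring = p$has_ring,
      ring_diameter_nm = ring_d, ring_protrusion_nm = ring_protrusion_nm,
      b_nm_per_rad = b, turns = (r_max - r_min) / spacing
    )
  }
  h <- add_noise(h, noise_sd_nm, seed)
  img <- afm_image(h, pixel_nm,
                   metadata = list(seed = seed, preset = "spiral-field",
                                   noise_sd_nm = noise_sd_nm))
  list(image = img, truth = bind_rows(truth_rows))
}

#' Synthetic field of standalone rings
#'
#' Annular objects with outer diameters and heights drawn from the
#' configured laws (defaults: the pre-assembled ring statistics). Use a
#' point-mass diameter of 49.1 nm to emulate the wider rings that form
#' without a parent spiral.
#'
#' @param n_rings Number of rings.
#' @param diameter_mean_nm,diameter_sd_nm Outer-diameter law (nm).
#' @param height_mean_nm,height_sd_nm Height law (nm).
#' @param wall_nm Ring wall thickness (nm).
#' @inheritParams synth_spiral_field
#' @return List with `image` and `truth`.
#' @export
synth_ring_field <- function(n_rings = 50, field_nm = NULL, pixel_nm = 1.5,
                             diameter_mean_nm = 35.5, diameter_sd_nm = 2.9,
                             height_mean_nm = 9.6, height_sd_nm = 2.2,
                             wall_nm = 10, noise_sd_nm = 0.1, seed = 3) {
  n_rings <- check_count(n_rings, "n_rings")
  pars <- with_seed(class_seed(seed, "ring"), {
    tibble(
      object_id = seq_len(n_rings),
      diameter_nm = rtruncnorm_matched(n_rings, diameter_mean_nm,
                                       diameter_sd_nm,
                                       lower = 2 * wall_nm + 6),
      height_nm = rtruncnorm_matched(n_rings, height_mean_nm, height_sd_nm,
                                     lower = 1)
    )
  })
  if (is.null(field_nm)) {
    field_nm <- ceiling(sqrt(max(1, n_rings)) *
                          (diameter_mean_nm + 4 * diameter_sd_nm + 30) /
                          0.55)
    field_nm <- max(field_nm, max(pars$diameter_nm) + 40)
  }
  pos <- with_seed(class_seed(seed, "placement"),
                   place_centers(n_rings, field_nm, pars$diameter_nm / 2))
  pars <- dplyr::bind_cols(pars, pos)
  h <- blank_canvas(field_nm, pixel_nm)
  for (i in seq_len(n_rings)) {
    p <- pars[i, ]
    h <- stamp_annulus(h, pixel_nm, p$cx_nm, p$cy_nm, p$diameter_nm / 2,
                       max(0, p$diameter_nm / 2 - wall_nm), p$height_nm)
  }
  h <- add_noise(h, noise_sd_nm, seed)
  img <- afm_image(h, pixel_nm,
                   metadata = list(seed = seed, preset = "ring-field",
                                   noise_sd_nm = noise_sd_nm))
  pars$kind <- "ring"
  pars$wall_nm <- wall_nm
  list(image = img,
       truth = pars[, c("object_id", "kind", "cx_nm", "cy_nm",
                        "diameter_nm", "height_nm", "wall_nm")])
}

#' Synthetic field of straight filaments
#'
#' Non-overlapping straight filament segments of the configured width law,
#' used for width-recovery benchmarks and as frame zero of the growth
#' series.
#'
#' @param n_filaments Number of filaments.
#' @param length_range_nm Uniform law for filament lengths (nm).
#' @inheritParams synth_spiral_field
#' @return List with `image` and `truth` (`length_nm`, `width_nm`,
#'   orientation, endpoints).
#' @export
synth_filament_field <- function(n_filaments = 13, field_nm = NULL,
                                 pixel_nm = 2, width_mean_nm = 13.4,
                                 width_sd_nm = 0.9,
                                 length_range_nm = c(120, 300),
                                 height_nm = 5.5, noise_sd_nm = 0.1,
                                 seed = 2) {
  n_filaments <- check_count(n_filaments, "n_filaments")
  pars <- with_seed(class_seed(seed, "filament"), {
    tibble(
      object_id = seq_len(n_filaments),
      width_nm = rtruncnorm_matched(n_filaments, width_mean_nm,
                                    width_sd_nm, lower = 2),
      length_nm = runif(n_filaments, length_range_nm[1],
                        length_range_nm[2]),
      angle_deg = runif(n_filaments, 0, 180)
    )
  })
  if (is.null(field_nm)) {
    field_nm <- ceiling(sqrt(n_filaments) *
                          (max(length_range_nm) + 40) / 0.8)
  }
  pos <- with_seed(class_seed(seed, "placement"),
                   place_centers(n_filaments, field_nm,
                                 pars$length_nm / 2 + pars$width_nm,
                                 margin_nm = 10))
  pars <- dplyr::bind_cols(pars, pos)
  h <- blank_canvas(field_nm, pixel_nm)
  for (i in seq_len(n_filaments)) {
    p <- pars[i, ]
    u <- c(cos(deg2rad(p$angle_deg)), sin(deg2rad(p$angle_deg)))
    h <- stamp_segment(h, pixel_nm,
                       p$cx_nm - p$length_nm / 2 * u[1],
                       p$cy_nm - p$length_nm / 2 * u[2],
                       p$cx_nm + p$length_nm / 2 * u[1],
                       p$cy_nm + p$length_nm / 2 * u[2],
                       p$width_nm / 2, height_nm)
  }
  h <- add_noise(h, noise_sd_nm, seed)
  img <- afm_image(h, pixel_nm,
                   metadata = list(seed = seed, preset = "filament-field",
                                   noise_sd_nm = noise_sd_nm))
  pars$kind <- "filament"
  pars$height_nm <- height_nm
  list(image = img,
       truth = pars[, c("object_id", "kind", "cx_nm", "cy_nm", "length_nm",
                        "width_nm", "angle_deg", "height_nm")])
}

#' Synthetic AFM time series of growing filaments
#'
#' Straight filaments elongate from one tip at per-filament constant
#' velocities drawn from the configured law (default: moment-matched
#' truncated normal reproducing the measured 24 +/- 19.6 nm/s). Fields are
#' sized so filaments do not collide at their final lengths.
#'
#' @param n_frames Number of frames (>= 3).
#' @param dt_s Frame interval (s).
#' @param n_filaments Number of filaments (11, as measured).
#' @param velocity_mean_nm_s,velocity_sd_nm_s Velocity law (nm/s),
#'   truncated at 0.
#' @param length0_range_nm Uniform law for initial lengths (nm).
#' @inheritParams synth_filament_field
#' @return List with `frames` (list of [afm_image()]), `dt_s` and `truth`
#'   (per-filament velocity and geometry).
#' @export
synth_growth_series <- function(n_frames = 10, dt_s = 0.25,
                                n_filaments = 11,
                                velocity_mean_nm_s = 24,
                                velocity_sd_nm_s = 19.6,
                                length0_range_nm = c(80, 150),
                                width_mean_nm = 13.4, width_sd_nm = 0.9,
                                pixel_nm = 2, height_nm = 5.5,
                                noise_sd_nm = 0.1, seed = 7) {
  n_frames <- check_count(n_frames, "n_frames", lower = 3L)
  check_number(dt_s, "dt_s")
  if (dt_s <= 0) stop_invalid("`dt_s` must be > 0.")
  pars <- with_seed(class_seed(seed, "filament"), {
    tibble(
      object_id = seq_len(n_filaments),
      velocity_nm_s = rtruncnorm_matched(n_filaments, velocity_mean_nm_s,
                                         velocity_sd_nm_s, lower = 0),
      length0_nm = runif(n_filaments, length0_range_nm[1],
                         length0_range_nm[2]),
      width_nm = rtruncnorm_matched(n_filaments, width_mean_nm,
                                    width_sd_nm, lower = 2),
      angle_deg = runif(n_filaments, 0, 180)
    )
  })
  t_total <- (n_frames - 1) * dt_s
  final_len <- pars$length0_nm + pars$velocity_nm_s * t_total
  # growth is one-sided, so the far tip reaches final_len - length0/2 from
  # the placed centre
  reach <- pmax(final_len - pars$length0_nm / 2, pars$length0_nm / 2) +
    pars$width_nm
  field_nm <- ceiling(sqrt(sum((2 * reach + 30)^2) / 0.35))
  pos <- with_seed(class_seed(seed, "placement"),
                   place_centers(n_filaments, field_nm, reach,
                                 margin_nm = 10))
  pars <- dplyr::bind_cols(pars, pos)
  frames <- map(seq_len(n_frames), function(f) {
    t_s <- (f - 1) * dt_s
    h <- blank_canvas(field_nm, pixel_nm)
    for (i in seq_len(n_filaments)) {
      p <- pars[i, ]
      u <- c(cos(deg2rad(p$angle_deg)), sin(deg2rad(p$angle_deg)))
      len <- p$length0_nm + p$velocity_nm_s * t_s
      # fixed tip at -length0/2 from the centre; growth extends the other tip
      h <- stamp_segment(h, pixel_nm,
                         p$cx_nm - p$length0_nm / 2 * u[1],
                         p$cy_nm - p$length0_nm / 2 * u[2],
                         p$cx_nm + (len - p$length0_nm / 2) * u[1],
                         p$cy_nm + (len - p$length0_nm / 2) * u[2],
                         p$width_nm / 2, height_nm)
    }
    h <- add_noise(h, noise_sd_nm, seed + 7919L * f)
    afm_image(h, pixel_nm,
              metadata = list(seed = seed, preset = "growth", frame = f,
                              t_s = t_s, noise_sd_nm = noise_sd_nm))
  })
  pars$kind <- "filament"
  list(frames = frames, dt_s = dt_s,
       truth = pars[, c("object_id", "kind", "cx_nm", "cy_nm",
                        "velocity_nm_s", "length0_nm", "width_nm",
                        "angle_deg")])
}
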