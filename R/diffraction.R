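#' Predict layer-line heights for a helical symmetry
#'
#' The Fourier transform of a helical lattice is confined to layer lines at
#' reciprocal axial heights `Z = (n * twist/360 + m) / rise`, where n is the
#' Bessel order (equal in magnitude to the start count of the matching
#' real-space family) and m the axial index. Only peak positions are
#' modelled; Bessel-function amplitude envelopes depend on the subunit shape
#' and are not predicted.
#'
#' @inheritParams start_family
#' @param n_range,m_range Integer vectors of Bessel orders and axial indices
#'   to enumerate.
#' @param z_max_invA Keep lines with `0 <= Z <= z_max_invA`; default is the
#'   Nyquist height for a 1.1 Å pixel.
#' @return Tibble (`n`, `m`, `Z_invA`, `spacing_A` = 1/Z) sorted by Z.
#' @examples
#' sym <- helical_symmetry(2.159, 85.495)
#' layer_lines(sym, n_range = c(-4, 0, 17), m_range = -4:4)
#' @export
layer_lines <- function(sym, n_range = -25:25, m_range = -6:6,
                        z_max_invA = 1 / (2 * 1.1)) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (length(n_range) < 1 || length(m_range) < 1) {
    stop_invalid("`n_range` and `m_range` must be non-empty.")
  }
  check_number(z_max_invA, "z_max_invA", lower = 0)
  grid <- expand_grid(n = as.integer(n_range), m = as.integer(m_range))
  grid$Z_invA <- (grid$n * sym$twist_deg / 360 + grid$m) / sym$rise_A
  grid <- grid[grid$Z_invA >= 0 & grid$Z_invA <= z_max_invA, ]
  grid$spacing_A <- ifelse(grid$Z_invA == 0, Inf, 1 / grid$Z_invA)
  arrange(as_tibble(grid), .data$Z_invA)
}

#' Solve the candidate-symmetry grid from indexed layer lines
#'
#' Given indexed reflections (reciprocal height Z and Bessel order n), every
#' pair of reflections plus an assignment of axial indices (m_i, m_j) from
#' the search grid determines a unique (rise, twist) through the two linear
#' equations `Z = (n * twist/360 + m) / rise`. All assignments on the m grid
#' are solved, solutions outside the bounds are dropped, duplicates are
#' merged (within 0.005 Å / 0.01 deg), and the survivors are ranked by their
#' RMS height residual against all reflections (each reflection assigned its
#' best integer m). This reproduces the systematic grid of possible
#' symmetries that helical indexing produces for subsequent refinement.
#'
#' @param reflections Data frame with columns `Z_invA` and `n`; at least two
#'   reflections with distinct n are required.
#' @param m_range Integer vector of axial indices searched (default -6..6).
#' @param rise_bounds_A,twist_bounds_deg Length-2 numeric bounds on the
#'   solutions (defaults 1-10 Å and (-180, 180] deg).
#' @return Tibble (`rise_A`, `twist_deg`, `residual_invA`, `m_assignment`
#'   list-column) ranked by residual; empty when nothing lies in bounds.
#' @examples
#' sym <- helical_symmetry(2.159, 85.495)
#' refl <- layer_lines(sym, n_range = c(-4, 17), m_range = -6:6)
#' refl <- refl[refl$n != 0 & refl$Z_invA > 0, ][1:2, c("Z_invA", "n")]
#' symmetry_candidates(refl)[1, ]
#' @export
symmetry_candidates <- function(reflections, m_range = -6:6,
                                rise_bounds_A = c(1, 10),
                                twist_bounds_deg = c(-180, 180)) {
  reflections <- as_tibble(reflections)
  if (!all(c("Z_invA", "n") %in% names(reflections))) {
    stop_invalid("`reflections` needs columns Z_invA and n.")
  }
  if (nrow(reflections) < 2 || length(unique(reflections$n)) < 2) {
    stop_invalid("need >= 2 reflections with distinct Bessel orders.")
  }
  m_range <- as.integer(m_range)
  Z <- reflections$Z_invA
  n <- reflections$n
  pairs <- utils::combn(seq_along(Z), 2)
  sols <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (n[i] == n[j]) next
    # [Z_i  -n_i/360] [rise ]   [m_i]
    # [Z_j  -n_j/360] [twist] = [m_j]
    A <- matrix(c(Z[i], Z[j], -n[i] / 360, -n[j] / 360), 2, 2)
    det_A <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    if (abs(det_A) < 1e-14) next
    Ainv <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2, 2) / det_A
    grid <- expand_grid(m_i = m_range, m_j = m_range)
    rise <- Ainv[1, 1] * grid$m_i + Ainv[1, 2] * grid$m_j
    twist <- Ainv[2, 1] * grid$m_i + Ainv[2, 2] * grid$m_j
    ok <- is.finite(rise) & is.finite(twist) &
      rise >= rise_bounds_A[1] & rise <= rise_bounds_A[2]
    if (!any(ok)) next
    twist_red <- reduce_angle(twist[ok])
    keep <- twist_red != 0 &
      twist_red > twist_bounds_deg[1] - 1e-12 &
      twist_red <= twist_bounds_deg[2] + 1e-12
    sols[[length(sols) + 1L]] <- tibble(rise_A = rise[ok][keep],
                                        twist_deg = twist_red[keep])
  }
  if (length(sols) == 0) {
    return(tibble(rise_A = numeric(), twist_deg = numeric(),
                  residual_invA = numeric(), m_assignment = list()))
  }
  cand <- bind_rows(sols)
  # residual of each candidate against all reflections, best integer m each
  res <- map(seq_len(nrow(cand)), function(i) {
    rise <- cand$rise_A[i]; twist <- cand$twist_deg[i]
    m_best <- round(Z * rise - n * twist / 360)
    dz <- Z - (n * twist / 360 + m_best) / rise
    list(rms = sqrt(mean(dz^2)), m = as.integer(m_best))
  })
  cand$residual_invA <- map_dbl(res, "rms")
  cand$m_assignment <- map(res, "m")
  # de-duplicate within tolerance (0.005 Angstrom, 0.01 deg), keep best;
  # residuals below solver precision are ties, broken toward smaller rise
  # (finer lattices subsume coarser sublattice aliases)
  cand$.key <- paste(round(cand$rise_A / 0.005), round(cand$twist_deg / 0.01))
  cand <- cand |>
    arrange(round(.data$residual_invA / 1e-12), .data$rise_A) |>
    distinct(.data$.key, .keep_all = TRUE) |>
    select(-".key")
  cand
}

#' Simulate the power spectrum of a projected helical lattice
#'
#' Renders a 2D projection of Gaussian pseudo-subunits placed on the helical
#' lattice (axial coordinate j*rise, horizontal coordinate
#' `radius * cos(azimuth)`), applies a Hann window, and returns the
#' origin-centred amplitude spectrum. Peak maxima fall on the predicted
#' layer-line heights; amplitudes are not physically modelled.
#'
#' @inheritParams lattice_vector
#' @param radius_A Filament radius used for the projection (Å).
#' @param image_size_px Square image size (>= 64 pixels).
#' @param pixel_A Pixel size (Å), > 0.
#' @param sigma_A Gaussian pseudo-subunit width (Å).
#' @param seed Integer seed (fixes the random azimuthal phase).
#' @return A `power_spectrum` object: list with `amplitude` (matrix, rows =
#'   Z), `freq_z_invA`, `freq_x_invA`, `pixel_A`.
#' @export
simulate_power_spectrum <- function(sym, radius_A, image_size_px = 512,
                                    pixel_A = 1.1, sigma_A = 8, seed = 1) {
  stopifnot(inherits(sym, "helical_symmetry"))
  check_number(radius_A, "radius_A", lower = 0)
  image_size_px <- check_count(image_size_px, "image_size_px", lower = 64L)
  check_number(pixel_A, "pixel_A")
  if (pixel_A <= 0) stop_invalid("`pixel_A` must be > 0.")
  height_A <- image_size_px * pixel_A
  n_sub <- floor(height_A / sym$rise_A)
  if (n_sub > 1e6) {
    abort("lattice would contain more than 1e6 subunits in the field",
          class = "vippgeom_resource_limit")
  }
  if (n_sub * sym$rise_A < 3 * abs(360 / sym$twist_deg) * sym$rise_A) {
    # fewer than ~3 turns of the 1-start; still proceed, peaks just broaden
  }
  phi0 <- with_seed(class_seed(seed, "spectrum"), runif(1, 0, 360))
  j <- seq_len(n_sub) - 1
  z_A <- j * sym$rise_A
  x_A <- radius_A * cos(deg2rad(phi0 + j * sym$twist_deg)) +
    height_A / 2
  img <- matrix(0, image_size_px, image_size_px) # [row = z, col = x]
  half_w <- max(3L, ceiling(3 * sigma_A / pixel_A))
  off <- (-half_w):half_w
  gauss1d <- function(d_px) exp(-(d_px * pixel_A)^2 / (2 * sigma_A^2))
  for (s in seq_len(n_sub)) {
    rz <- z_A[s] / pixel_A + 1
    cx <- x_A[s] / pixel_A + 1
    rows <- round(rz) + off
    cols <- round(cx) + off
    okr <- rows >= 1 & rows <= image_size_px
    okc <- cols >= 1 & cols <= image_size_px
    if (!any(okr) || !any(okc)) next
    gz <- gauss1d(rows[okr] - rz)
    gx <- gauss1d(cols[okc] - cx)
    img[rows[okr], cols[okc]] <- img[rows[okr], cols[okc]] + gz %o% gx
  }
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  w <- hann(image_size_px)
  amp <- Mod(fft((img - mean(img)) * (w %o% w)))
  # centre the origin
  shift <- function(m) {
    n <- nrow(m); h <- floor(n / 2)
    m[c((h + 1):n, 1:h), c((h + 1):n, 1:h)]
  }
  amp <- shift(amp)
  freq <- (seq_len(image_size_px) - 1 - floor(image_size_px / 2)) /
    (image_size_px * pixel_A)
  structure(list(amplitude = amp, freq_z_invA = freq, freq_x_invA = freq,
                 pixel_A = pixel_A),
            class = "power_spectrum")
}

#' Layer-line profile of a simulated power spectrum
#'
#' Collapses a [simulate_power_spectrum()] result to the maximum amplitude at
#' each reciprocal axial height Z, the quantity used to read layer-line
#' positions.
#'
#' @param spec A `power_spectrum`.
#' @return Tibble (`Z_invA`, `amplitude`).
#' @export
layer_line_profile <- function(spec) {
  stopifnot(inherits(spec, "power_spectrum"))
  tibble(Z_invA = spec$freq_z_invA,
         amplitude = apply(spec$amplitude, 1, max))
}

#' @exportS3Method ggplot2::autoplot
autoplot.power_spectrum <- function(object, trans = function(x) log1p(x),
                                    ...) {
  df <- expand_grid(Z_invA = object$freq_z_invA,
                    R_invA = object$freq_x_invA)
  df$amplitude <- trans(as.vector(t(object$amplitude)))
  ggplot(df, aes(.data$R_invA, .data$Z_invA, fill = .data$amplitude)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "R (1/Angstrom)", y = "Z (1/Angstrom)",
         fill = "log amplitude") +
    theme_minimal()
}
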