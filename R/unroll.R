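#' Unroll a helical lattice into its equivalent planar lattice
#'
#' Maps subunit j of the helix to the plane via
#' `(x, y) = (radius * azimuth, j * rise)` with the azimuth wrapped to
#' `[0, 2*pi)` (origin on the +x axis, y increasing with z). The set of
#' nearest-neighbour displacements of the unrolled points equals the
#' lattice-vector set of the helical surface lattice, so the 3D polymer can
#' be compared directly with membrane-bound planar sheets and spirals.
#'
#' @inheritParams lattice_vector
#' @param n_subunits Number of subunits to place (>= 1).
#' @param radius_A Unrolling radius (Å, > 0).
#' @param phi0_deg Azimuth of subunit 0 (degrees).
#' @return An `unrolled_lattice`: tibble (`j`, `x_A`, `y_A`) with attributes
#'   `radius_A` and `sym`.
#' @examples
#' sym <- helical_symmetry(2.159, 85.495)
#' ul <- unroll_points(sym, 200, 92.75)
#' @export
unroll_points <- function(sym, n_subunits, radius_A, phi0_deg = 0) {
  stopifnot(inherits(sym, "helical_symmetry"))
  n_subunits <- check_count(n_subunits, "n_subunits")
  check_number(radius_A, "radius_A")
  if (radius_A <= 0) stop_invalid("`radius_A` must be > 0.")
  j <- seq_len(n_subunits) - 1
  phi <- (phi0_deg + j * sym$twist_deg) %% 360
  out <- tibble(j = j, x_A = radius_A * deg2rad(phi), y_A = j * sym$rise_A)
  structure(out, radius_A = radius_A, sym = sym,
            class = c("unrolled_lattice", class(out)))
}

#' Re-roll unrolled lattice points back onto the cylinder
#'
#' Inverse of [unroll_points()]: recovers azimuth (deg, in [0, 360)) and
#' axial position from planar coordinates.
#'
#' @param unrolled An `unrolled_lattice` (or tibble with `x_A`, `y_A` and a
#'   `radius_A` attribute).
#' @return Tibble (`phi_deg`, `z_A`).
#' @export
reroll_points <- function(unrolled) {
  r <- attr(unrolled, "radius_A")
  if (is.null(r)) stop_invalid("input carries no `radius_A` attribute.")
  tibble(phi_deg = rad2deg(unrolled$x_A / r) %% 360, z_A = unrolled$y_A)
}

#' @exportS3Method ggplot2::autoplot
autoplot.unrolled_lattice <- function(object, ...) {
  ggplot(object, aes(.data$x_A, .data$y_A)) +
    geom_point(size = 0.8) +
    coord_equal() +
    labs(x = "r * azimuth (Angstrom)", y = "z (Angstrom)") +
    theme_minimal()
}

#' Cylindrical projection (unrolling) of a 3D density map
#'
#' Samples the density on a cylindrical shell of the given radius and mean
#' radial thickness and lays it out as a 2D raster indexed by azimuth and
#' height: output pixel (theta, z) is the mean density over the radial shell
#' `[radius - dr/2, radius + dr/2]`, trilinear interpolation, azimuth origin
#' on the +x axis, sampled at least at the Nyquist rate for the voxel size.
#'
#' @param map3d A density map as returned by [read_density_map()] or
#'   [synthetic_lattice_map()]: list with `data` (3D array, x fastest) and
#'   `voxel_A` (length-3).
#' @param radius_A Shell radius (Å); the full shell must fit inside the map.
#' @param shell_dr_A Radial thickness averaged over (Å, > 0); default two
#'   voxels.
#' @param center_A Optional cylinder axis position `(x, y)` in Å; defaults
#'   to the raster centre.
#' @return An `unrolled_map`: list with `data` (matrix, rows = azimuth
#'   samples, cols = z), `pixel_A_x` (azimuthal arc step), `pixel_A_y`,
#'   `radius_A`.
#' @export
unroll_map <- function(map3d, radius_A, shell_dr_A = NULL, center_A = NULL) {
  stopifnot(is.list(map3d), !is.null(map3d$data), !is.null(map3d$voxel_A))
  vol <- map3d$data
  vx <- rep(map3d$voxel_A, length.out = 3)
  check_number(radius_A, "radius_A")
  if (is.null(shell_dr_A)) shell_dr_A <- 2 * min(vx[1:2])
  check_number(shell_dr_A, "shell_dr_A")
  if (shell_dr_A <= 0) stop_invalid("`shell_dr_A` must be > 0.")
  dims <- dim(vol)
  ext <- dims * vx # physical extent, Angstrom
  if (is.null(center_A)) center_A <- ext[1:2] / 2
  r_out <- radius_A + shell_dr_A / 2
  half_min <- min(center_A[1], ext[1] - center_A[1],
                  center_A[2], ext[2] - center_A[2])
  if (radius_A <= 0 || r_out + max(vx[1:2]) > half_min) {
    stop_invalid("shell radius does not fit inside the map raster.")
  }
  n_theta <- max(8L, ceiling(2 * 2 * pi * radius_A / min(vx[1:2])))
  theta <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  r_samp <- seq(radius_A - shell_dr_A / 2, radius_A + shell_dr_A / 2,
                by = min(vx[1:2]) / 2)
  if (length(r_samp) < 2) r_samp <- radius_A
  nz <- dims[3]
  out <- matrix(0, n_theta, nz)
  # fractional voxel indices (1-based, voxel centres at (i - 0.5) * voxel)
  zi <- seq_len(nz) # z planes sampled at their own centres
  for (r in r_samp) {
    xf <- (center_A[1] + r * cos(theta)) / vx[1] + 0.5
    yf <- (center_A[2] + r * sin(theta)) / vx[2] + 0.5
    out <- out + bilinear_xy_stack(vol, xf, yf)
  }
  out <- out / length(r_samp)
  structure(list(data = out, pixel_A_x = 2 * pi * radius_A / n_theta,
                 pixel_A_y = vx[3], radius_A = radius_A),
            class = "unrolled_map")
}

# Interpolate vol (3D) at positions (xf[i], yf[i]) for every z plane;
# returns matrix [length(xf), nz]. Sampling z at plane centres makes the
# "trilinear" interpolation exact in z.
bilinear_xy_stack <- function(vol, xf, yf) {
  dims <- dim(vol)
  x0 <- pmin(pmax(floor(xf), 1L), dims[1] - 1L)
  y0 <- pmin(pmax(floor(yf), 1L), dims[2] - 1L)
  tx <- pmin(pmax(xf - x0, 0), 1)
  ty <- pmin(pmax(yf - y0, 0), 1)
  nz <- dims[3]
  out <- matrix(0, length(xf), nz)
  for (z in seq_len(nz)) {
    sl <- vol[, , z]
    i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1L, y0)
    i01 <- cbind(x0, y0 + 1L); i11 <- cbind(x0 + 1L, y0 + 1L)
    out[, z] <- sl[i00] * (1 - tx) * (1 - ty) + sl[i10] * tx * (1 - ty) +
      sl[i01] * (1 - tx) * ty + sl[i11] * tx * ty
  }
  out
}

#' Synthetic density map of Gaussian blobs on a helical lattice
#'
#' Builds a 3D raster with Gaussian pseudo-subunits centred on the helical
#' lattice points at the given radius; used as a self-contained fixture for
#' validating [unroll_map()] against the analytic planar lattice.
#'
#' @inheritParams unroll_points
#' @param box_px Cube side (voxels).
#' @param voxel_A Voxel size (Å, scalar or length-3).
#' @param sigma_A Gaussian subunit width (Å).
#' @return A map list (`data`, `voxel_A`) compatible with [unroll_map()] and
#'   [write_density_map()].
#' @export
synthetic_lattice_map <- function(sym, radius_A, box_px = 96, voxel_A = 2,
                                  sigma_A = 4, phi0_deg = 0) {
  stopifnot(inherits(sym, "helical_symmetry"))
  box_px <- check_count(box_px, "box_px", lower = 8L)
  vx <- rep(voxel_A, length.out = 3)
  ext <- box_px * vx
  n_sub <- floor(ext[3] / sym$rise_A)
  j <- seq_len(n_sub) - 1
  phi <- deg2rad(phi0_deg + j * sym$twist_deg)
  cx <- ext[1] / 2 + radius_A * cos(phi)
  cy <- ext[2] / 2 + radius_A * sin(phi)
  cz <- j * sym$rise_A
  vol <- array(0, dim = c(box_px, box_px, box_px))
  half <- ceiling(3 * sigma_A / min(vx))
  ax <- (seq_len(box_px) - 0.5) # voxel centres in voxel units
  for (s in seq_len(n_sub)) {
    ix <- round(cx[s] / vx[1]); iy <- round(cy[s] / vx[2])
    iz <- round(cz[s] / vx[3])
    rx <- max(1, ix - half):min(box_px, ix + half)
    ry <- max(1, iy - half):min(box_px, iy + half)
    rz <- max(1, iz - half):min(box_px, iz + half)
    if (!length(rx) || !length(ry) || !length(rz)) next
    gx <- exp(-((ax[rx] * vx[1] - cx[s])^2) / (2 * sigma_A^2))
    gy <- exp(-((ax[ry] * vx[2] - cy[s])^2) / (2 * sigma_A^2))
    gz <- exp(-((ax[rz] * vx[3] - cz[s])^2) / (2 * sigma_A^2))
    vol[rx, ry, rz] <- vol[rx, ry, rz] + gx %o% gy %o% gz
  }
  list(data = vol, voxel_A = vx)
}

#' Line-family spacings of an unrolled lattice
#'
#' For each requested start family k, estimates from the unrolled point set
#' the direction of the k-connected strand lines, the perpendicular spacing
#' between adjacent parallel lines, the axial (along-y) spacing, and the
#' line tilt from horizontal. On a noiseless lattice the axial spacing
#' equals the family's closed-form `360 * rise / |step|`.
#'
#' @param unrolled An `unrolled_lattice` from [unroll_points()] (or any
#'   tibble with `x_A`, `y_A` and a `radius_A` attribute; use
#'   `radius_A = Inf` for a non-wrapping planar fixture). At least 10 points.
#' @param k_families Integer vector of connection indices to measure.
#' @return Tibble (`k`, `perpendicular_spacing_A`, `axial_spacing_A`,
#'   `tilt_deg`).
#' @export
line_family_spacings <- function(unrolled, k_families) {
  if (nrow(unrolled) < 10) stop_invalid("need at least 10 points.")
  r <- attr(unrolled, "radius_A")
  if (is.null(r)) stop_invalid("input carries no `radius_A` attribute.")
  period <- if (is.finite(r)) 2 * pi * r else Inf
  x <- unrolled$x_A
  y <- unrolled$y_A
  if (sd(x) < 1e-12 && sd(y) < 1e-12) {
    abort("degenerate point set: all points coincide.",
          class = "vippgeom_degenerate")
  }
  rows <- map(as.integer(k_families), function(k) {
    if (k >= nrow(unrolled)) {
      return(tibble(k = k, perpendicular_spacing_A = NA_real_,
                    axial_spacing_A = NA_real_, tilt_deg = NA_real_))
    }
    idx <- seq_len(nrow(unrolled) - k)
    dx <- x[idx + k] - x[idx]
    dy <- y[idx + k] - y[idx]
    if (is.finite(period)) dx <- dx - period * round(dx / period)
    # componentwise median: robust to the occasional incongruent step in
    # hand-ordered planar fixtures (e.g. row-major grids)
    u <- c(median(dx), median(dy))
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) {
      abort("degenerate family direction (collinear input).",
            class = "vippgeom_degenerate")
    }
    u <- u / nu
    nvec <- c(-u[2], u[1])
    s <- sort(x * nvec[1] + y * nvec[2])
    d <- diff(s)
    tol <- max(1e-6, 0.05 * max(d))
    gaps <- d[d > tol]
    if (!length(gaps)) {
      abort("degenerate input: all points fall on a single line.",
            class = "vippgeom_degenerate")
    }
    perp <- median(gaps)
    tilt <- rad2deg(atan2(abs(u[2]), abs(u[1])))
    axial <- if (abs(u[1]) > 1e-9) perp / abs(u[1]) else Inf
    tibble(k = k, perpendicular_spacing_A = perp,
           axial_spacing_A = axial, tilt_deg = tilt)
  })
  bind_rows(rows)
}
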