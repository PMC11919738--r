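#' Helical symmetry of a filament lattice
#'
#' A helical polymer is described by its rise (axial translation per subunit,
#' in ångström) and twist (azimuthal rotation per subunit, in degrees,
#' reduced to the interval (-180, 180]). Optional lumen and outer wall radii
#' bound the filament wall; lattice vectors are usually evaluated at the
#' mid-wall radius.
#'
#' @param rise_A Axial rise per subunit (Å), must be > 0.
#' @param twist_deg Azimuthal rotation per subunit (degrees); reduced to
#'   (-180, 180] and must not reduce to 0.
#' @param r_lumen_A,r_outer_A Optional inner (lumen) and outer radii (Å);
#'   if both are given, `0 < r_lumen_A < r_outer_A` is required.
#' @param label Free-text label for the filament.
#' @return An object of class `helical_symmetry`.
#' @examples
#' sym <- helical_symmetry(2.159, 85.495, r_lumen_A = 63.5, r_outer_A = 122)
#' sym
#' @export
helical_symmetry <- function(rise_A, twist_deg, r_lumen_A = NA_real_,
                             r_outer_A = NA_real_, label = "") {
  check_number(rise_A, "rise_A")
  if (rise_A <= 0) stop_invalid("`rise_A` must be > 0.")
  check_number(twist_deg, "twist_deg")
  twist_deg <- reduce_angle(twist_deg)
  if (twist_deg == 0) stop_invalid("`twist_deg` must not reduce to 0.")
  if (!is.na(r_lumen_A) || !is.na(r_outer_A)) {
    if (!is.na(r_lumen_A)) check_number(r_lumen_A, "r_lumen_A")
    if (!is.na(r_outer_A)) check_number(r_outer_A, "r_outer_A")
    if (!is.na(r_lumen_A) && !is.na(r_outer_A) &&
        !(0 < r_lumen_A && r_lumen_A < r_outer_A)) {
      stop_invalid("radii must satisfy 0 < r_lumen_A < r_outer_A.")
    }
  }
  structure(
    list(rise_A = rise_A, twist_deg = twist_deg,
         r_lumen_A = r_lumen_A, r_outer_A = r_outer_A, label = label),
    class = "helical_symmetry"
  )
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("<helical_symmetry> %s\n", if (nzchar(x$label)) x$label else ""))
  cat(sprintf("  rise  %.4f Angstrom / subunit\n", x$rise_A))
  cat(sprintf("  twist %+.4f deg / subunit\n", x$twist_deg))
  if (!is.na(x$r_lumen_A) || !is.na(x$r_outer_A)) {
    cat(sprintf("  radii lumen %.1f, outer %.1f Angstrom (mid-wall %.2f)\n",
                x$r_lumen_A, x$r_outer_A, mid_wall_radius(x)))
  }
  invisible(x)
}

#' Reduce an angle to the interval (-180, 180] degrees
#'
#' @param angle_deg Numeric vector of angles in degrees (finite).
#' @return Angles congruent to the input modulo 360, in (-180, 180].
#' @examples
#' reduce_angle(341.98)  # -18.02
#' reduce_angle(360)     # 0
#' @export
reduce_angle <- function(angle_deg) {
  if (!is.numeric(angle_deg) || any(!is.finite(angle_deg))) {
    stop_invalid("`angle_deg` must be finite numeric.")
  }
  r <- angle_deg %% 360
  r[r > 180] <- r[r > 180] - 360
  r
}

#' Mid-wall radius of a helical filament
#'
#' @param sym A [helical_symmetry()] with both radii set, or a numeric lumen
#'   radius (Å).
#' @param r_outer_A Outer radius (Å) when `sym` is numeric.
#' @return Radius halfway through the filament wall (Å).
#' @export
mid_wall_radius <- function(sym, r_outer_A = NULL) {
  if (inherits(sym, "helical_symmetry")) {
    if (is.na(sym$r_lumen_A) || is.na(sym$r_outer_A)) {
      stop_invalid("both radii must be set to compute a mid-wall radius.")
    }
    return((sym$r_lumen_A + sym$r_outer_A) / 2)
  }
  (sym + r_outer_A) / 2
}

#' Start-helix families of a helical lattice
#'
#' Connecting every k-th subunit of a 1-start helix yields a family of k
#' parallel strands (a "k-start helix"). The azimuthal step per connection is
#' `k * twist` reduced to (-180, 180]; its sign gives the handedness (positive
#' step = right-handed in a z-up right-handed frame). The strand pitch is the
#' axial rise of one strand per full turn, and the axial spacing between
#' adjacent strands of the family is `pitch / k = 360 * rise / |step|`.
#'
#' @param sym A [helical_symmetry()].
#' @param k Positive integer connection index (vectorized).
#' @return A tibble with one row per `k`: `k`, `step_deg`, `handedness`
#'   ("right", "left" or "axial"), `rise_per_step_A`, `strand_pitch_A`,
#'   `axial_spacing_A` (`Inf` when the step is exactly 0).
#' @examples
#' sym <- helical_symmetry(2.159, 85.495)
#' start_family(sym, c(4, 17, 21))
#' @export
start_family <- function(sym, k) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 1) ||
      any(k != round(k))) {
    stop_invalid("`k` must be positive integer(s).")
  }
  k <- as.integer(k)
  step <- reduce_angle(k * sym$twist_deg)
  handed <- dplyr::case_when(step > 0 ~ "right", step < 0 ~ "left",
                             TRUE ~ "axial")
  axial <- ifelse(step == 0, Inf, 360 * sym$rise_A / abs(step))
  tibble(
    k = k,
    step_deg = step,
    handedness = handed,
    rise_per_step_A = k * sym$rise_A,
    strand_pitch_A = k * axial,
    axial_spacing_A = axial
  )
}

#' Find the start family running most nearly parallel to the helix axis
#'
#' Returns the connection index k in `[1, k_max]` whose reduced azimuthal
#' step is smallest in magnitude; ties break toward smaller k. Strands of
#' this family run closest to parallel with the filament axis.
#'
#' @inheritParams start_family
#' @param k_max Largest connection index searched (default 25, about the
#'   largest start count visible for the widest filament considered here:
#'   circumference / minimum subunit spacing).
#' @return Integer k.
#' @examples
#' near_axial_family(helical_symmetry(2.159, 85.495))  # 21
#' @export
near_axial_family <- function(sym, k_max = 25) {
  stopifnot(inherits(sym, "helical_symmetry"))
  k_max <- check_count(k_max, "k_max")
  fam <- start_family(sym, seq_len(k_max))
  fam$k[which.min(abs(fam$step_deg))]
}

#' Lattice vector of a start family on the unrolled surface
#'
#' On the cylinder unrolled at `radius_A`, connecting subunit j to j+k gives
#' a planar displacement with circumferential component
#' `radius * step(radians)` (signed) and axial component `k * rise`.
#'
#' @inheritParams start_family
#' @param radius_A Evaluation radius (Å, >= 0).
#' @return Tibble with `k`, `dx_A`, `dz_A`, `length_A`, `radius_A`.
#' @examples
#' lattice_vector(helical_symmetry(2.159, 85.495), c(4, 17), 92.75)
#' @export
lattice_vector <- function(sym, k, radius_A) {
  check_number(radius_A, "radius_A", lower = 0)
  fam <- start_family(sym, k)
  dx <- radius_A * deg2rad(fam$step_deg)
  dz <- fam$k * sym$rise_A
  tibble(
    k = fam$k, dx_A = dx, dz_A = dz,
    length_A = sqrt(dx^2 + dz^2), radius_A = radius_A
  )
}

#' Principal (nearest-neighbour) lattice vectors at a radius
#'
#' The two shortest lattice vectors over `k = 1..k_max` define the principal
#' directions of the surface lattice; their start counts match the dominant
#' Bessel orders of the diffraction pattern. Ordered by length; ties (within
#' 1e-9 Å) break toward smaller k.
#'
#' @inheritParams lattice_vector
#' @param k_max Largest connection index searched (default 25).
#' @return Two-row tibble (`role` = "short"/"long") with the lattice-vector
#'   columns plus `step_deg` and `handedness`.
#' @examples
#' sym <- helical_symmetry(2.159, 85.495, r_lumen_A = 63.5, r_outer_A = 122)
#' principal_vectors(sym, mid_wall_radius(sym))  # k = 4 and k = 17
#' @export
principal_vectors <- function(sym, radius_A, k_max = 25) {
  check_number(radius_A, "radius_A")
  if (radius_A <= 0) stop_invalid("`radius_A` must be > 0.")
  k_max <- check_count(k_max, "k_max", lower = 2L)
  vec <- lattice_vector(sym, seq_len(k_max), radius_A)
  fam <- start_family(sym, seq_len(k_max))
  vec$step_deg <- fam$step_deg
  vec$handedness <- fam$handedness
  ord <- order(round(vec$length_A / 1e-9), vec$k)
  out <- vec[ord[1:2], ]
  out$role <- c("short", "long")
  out[, c("role", "k", "dx_A", "dz_A", "length_A", "step_deg",
          "handedness", "radius_A")]
}

#' Subunit spacing of a start family at a radius
#'
#' Euclidean distance between k-connected subunits on the surface unrolled at
#' `radius_A`; monotone non-decreasing in the radius.
#'
#' @inheritParams lattice_vector
#' @return Numeric vector of spacings (Å), one per `k`.
#' @export
subunit_spacing_at_radius <- function(sym, k, radius_A) {
  lattice_vector(sym, k, radius_A)$length_A
}

#' Full start-family table with near-axial and principal flags
#'
#' One row per connection index up to `k_max` with step, handedness, pitch
#' and axial spacing, flagging the near-axial family and (when a radius is
#' available) the two principal nearest-neighbour families.
#'
#' @inheritParams near_axial_family
#' @param radius_A Evaluation radius (Å); defaults to the mid-wall radius
#'   when the symmetry carries both radii, otherwise principal flags and
#'   vector lengths are omitted.
#' @return Tibble with the [start_family()] columns plus `length_A` (at the
#'   evaluation radius, if any), `near_axial`, `principal`.
#' @export
start_family_table <- function(sym, k_max = 25, radius_A = NULL) {
  stopifnot(inherits(sym, "helical_symmetry"))
  k_max <- check_count(k_max, "k_max")
  fam <- start_family(sym, seq_len(k_max))
  fam$near_axial <- fam$k == near_axial_family(sym, k_max)
  if (is.null(radius_A) &&
      !is.na(sym$r_lumen_A) && !is.na(sym$r_outer_A)) {
    radius_A <- mid_wall_radius(sym)
  }
  if (!is.null(radius_A)) {
    fam$length_A <- subunit_spacing_at_radius(sym, fam$k, radius_A)
    pv <- principal_vectors(sym, radius_A, max(k_max, 2))
    fam$principal <- fam$k %in% pv$k
    fam$radius_A <- radius_A
  } else {
    fam$length_A <- NA_real_
    fam$principal <- NA
    fam$radius_A <- NA_real_
  }
  fam
}

#' Refined helical symmetries of the four Vipp1 filament lattices
#'
#' Helical rise and twist refined for the four cryo-EM filament
#' reconstructions, with outer and lumen radii where stated: the full-length
#' Vipp1 lattice L1, the interface-3 mutant F197K/L200K lattice L1, and the
#' two C-terminally truncated (delta-alpha6) lattices L2 and L3.
#'
#' @return Tibble with `label`, `rise_A`, `twist_deg`, `r_lumen_A`,
#'   `r_outer_A`.
#' @examples
#' syms <- vipp1_symmetries()
#' sym <- helical_symmetry(syms$rise_A[4], syms$twist_deg[4])
#' near_axial_family(sym)
#' @export
vipp1_symmetries <- function() {
  tibble(
    label = c("Vipp1_L1", "Vipp1_F197K/L200K_L1",
              "Vipp1_da6_L2", "Vipp1_da6_L3"),
    rise_A = c(2.372, 2.440, 2.155, 2.159),
    twist_deg = c(-75.860, -75.835, 68.507, 85.495),
    r_lumen_A = c(52.5, 52.5, NA, 63.5),
    r_outer_A = c(105, 105, NA, 122)
  )
}
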