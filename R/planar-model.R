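#' Inter-ridge spacing bounds of a planar filament
#'
#' The filament substructure is a set of parallel ridges with a relaxed
#' repeat `s0` (54 Å). Measurements across ring rungs show the repeat can
#' only compress to about `s_min` (41 Å) or stretch to about `s_max`
#' (61 Å); together with the filament width these bounds set how tightly a
#' strictly planar filament can bend in the membrane plane.
#'
#' @param s0_A Relaxed inter-ridge spacing (Å).
#' @param s_min_A,s_max_A Compression and stretch bounds (Å),
#'   `0 < s_min_A < s0_A < s_max_A`.
#' @param width_A Filament width (Å), > 0 (134 Å, i.e. 13.4 nm).
#' @return A `curvature_model` record.
#' @examples
#' curvature_model()
#' @export
curvature_model <- function(s0_A = 54, s_min_A = 41, s_max_A = 61,
                            width_A = 134) {
  check_number(s0_A, "s0_A"); check_number(s_min_A, "s_min_A")
  check_number(s_max_A, "s_max_A"); check_number(width_A, "width_A")
  if (!(0 < s_min_A && s_min_A < s0_A && s0_A < s_max_A)) {
    stop_invalid("need 0 < s_min_A < s0_A < s_max_A.")
  }
  if (width_A <= 0) stop_invalid("`width_A` must be > 0.")
  structure(list(s0_A = s0_A, s_min_A = s_min_A, s_max_A = s_max_A,
                 width_A = width_A),
            class = "curvature_model")
}

#' @export
print.curvature_model <- function(x, ...) {
  cat(sprintf(
    "<curvature_model> s0 %.1f A (bounds %.1f-%.1f), width %.1f A\n",
    x$s0_A, x$s_min_A, x$s_max_A, x$width_A))
  cat(sprintf("  minimum planar centerline diameter %.1f nm\n",
              min_planar_diameter(x)))
  invisible(x)
}

#' Ridge spacing across a bent filament
#'
#' When a filament of width w bends in plane with centerline radius R, the
#' rigid ridge elements pivot: spacing stays relaxed at the reference line
#' and scales with the local radius, shortening on the inside of the bend
#' and extending on the outside.
#'
#' @param centerline_radius_A Bend radius of the filament centerline (Å);
#'   must exceed half the width. Vectorized.
#' @param model A [curvature_model()].
#' @param reference `"centerline"` (default; spacing relaxed at the
#'   centerline) or `"inner"` (relaxed at the inner edge).
#' @return Tibble (`centerline_radius_A`, `s_inner_A`, `s_outer_A`).
#' @examples
#' spacing_across_bend(516.9)  # s_outer ~ 61
#' @export
spacing_across_bend <- function(centerline_radius_A,
                                model = curvature_model(),
                                reference = c("centerline", "inner")) {
  stopifnot(inherits(model, "curvature_model"))
  reference <- match.arg(reference)
  R <- centerline_radius_A
  if (!is.numeric(R) || any(!is.finite(R) & !is.infinite(R))) {
    stop_invalid("`centerline_radius_A` must be numeric.")
  }
  w <- model$width_A
  if (any(R <= w / 2)) {
    stop_invalid("centerline radius <= width/2: filament self-overlaps.")
  }
  ref_r <- switch(reference, centerline = R, inner = R - w / 2)
  s_in <- model$s0_A * (R - w / 2) / ref_r
  s_out <- model$s0_A * (R + w / 2) / ref_r
  s_in[is.infinite(R)] <- model$s0_A
  s_out[is.infinite(R)] <- model$s0_A
  tibble(centerline_radius_A = R, s_inner_A = s_in, s_outer_A = s_out)
}

#' Minimum centerline diameter of a strictly planar filament
#'
#' The tightest in-plane bend keeps the outer-edge spacing at or below
#' `s_max` and the inner-edge spacing at or above `s_min`:
#' `R_outer = s0 * (w/2) / (s_max - s0)` and
#' `R_inner = s0 * (w/2) / (s0 - s_min)`; the binding constraint is the
#' larger radius. With the default bounds the minimum planar centerline
#' diameter is about 103 nm — far wider than the central rings observed in
#' spirals, which is why those rings must tilt out of plane.
#'
#' @inheritParams spacing_across_bend
#' @param method `"closed_form"` (default) or `"scan"` (brute-force search
#'   over bend radii for the smallest feasible one, used as an independent
#'   cross-check).
#' @return Minimum planar centerline diameter in nm.
#' @examples
#' min_planar_diameter()  # ~103.4 nm
#' @export
min_planar_diameter <- function(model = curvature_model(),
                                reference = c("centerline", "inner"),
                                method = c("closed_form", "scan")) {
  stopifnot(inherits(model, "curvature_model"))
  reference <- match.arg(reference)
  method <- match.arg(method)
  w <- model$width_A
  if (w == 0) return(0)
  if (method == "closed_form" && reference == "centerline") {
    r_outer <- model$s0_A * (w / 2) / (model$s_max_A - model$s0_A)
    r_inner <- model$s0_A * (w / 2) / (model$s0_A - model$s_min_A)
    return(2 * max(r_outer, r_inner) / 10)
  }
  if (method == "closed_form" && reference == "inner") {
    # s relaxed at inner edge: s_outer = s0 * (R + w/2) / (R - w/2)
    r_outer <- (w / 2) * (model$s_max_A + model$s0_A) /
      (model$s_max_A - model$s0_A)
    return(2 * r_outer / 10)
  }
  # brute-force scan over centerline radii
  feasible <- function(R) {
    s <- spacing_across_bend(R, model, reference)
    s$s_inner_A >= model$s_min_A - 1e-12 &
      s$s_outer_A <= model$s_max_A + 1e-12
  }
  R_grid <- seq(w / 2 * 1.0001, w / 2 + 5000, by = 0.02)
  ok <- feasible(R_grid)
  if (!any(ok)) stop_invalid("no feasible planar bend radius found in scan.")
  2 * R_grid[which(ok)[1]] / 10
}

#' Does an observed ring diameter require out-of-plane tilt?
#'
#' TRUE when the observed (centerline) diameter is below the minimum
#' diameter a strictly planar filament can reach; a ring exactly at the
#' minimum is still feasible in plane.
#'
#' @param observed_diameter_nm Observed diameter (nm), > 0. Vectorized.
#' @inheritParams spacing_across_bend
#' @return Logical.
#' @examples
#' requires_tilt(37)   # TRUE: central rings must tilt
#' requires_tilt(200)  # FALSE
#' @export
requires_tilt <- function(observed_diameter_nm, model = curvature_model()) {
  if (!is.numeric(observed_diameter_nm) ||
      any(!is.finite(observed_diameter_nm)) ||
      any(observed_diameter_nm <= 0)) {
    stop_invalid("`observed_diameter_nm` must be positive.")
  }
  observed_diameter_nm < min_planar_diameter(model)
}

#' Sensitivity of the minimum planar diameter to the spacing bounds
#'
#' The compression/stretch bounds are approximate; this reports the minimum
#' planar diameter over a +/- delta grid on each bound.
#'
#' @inheritParams spacing_across_bend
#' @param delta_A Half-width of the grid on each bound (Å).
#' @param step_A Grid step (Å).
#' @return Tibble (`s_min_A`, `s_max_A`, `min_planar_diameter_nm`).
#' @export
min_planar_diameter_sensitivity <- function(model = curvature_model(),
                                            delta_A = 2, step_A = 1) {
  grid <- expand_grid(
    s_min_A = model$s_min_A + seq(-delta_A, delta_A, by = step_A),
    s_max_A = model$s_max_A + seq(-delta_A, delta_A, by = step_A)
  )
  grid$min_planar_diameter_nm <- purrr::pmap_dbl(grid, function(s_min_A,
                                                                s_max_A) {
    m <- curvature_model(model$s0_A, s_min_A, s_max_A, model$width_A)
    min_planar_diameter(m)
  })
  grid
}

#' C_N ring geometry
#'
#' A ring rung with N-fold rotational symmetry places N subunits around its
#' circumference, so `pi * diameter = N * subunit_arc` at any stated radius.
#' Exactly one of `diameter_A` or `subunit_arc_A` must be given; the other
#' is computed.
#'
#' @param N Rotational symmetry order (integer >= 3).
#' @param diameter_A Ring diameter (Å) at the radius of interest.
#' @param subunit_arc_A Arc length per subunit (Å) at that radius.
#' @param rung_spacing_A Axial spacing between stacked rungs (Å; 32.5 from
#'   the 32-33 Å inter-filament repeat).
#' @param n_rungs Optional number of rungs.
#' @return A one-row tibble (`N`, `diameter_A`, `subunit_arc_A`,
#'   `rung_spacing_A`, `n_rungs`, `height_A` when `n_rungs` given).
#' @examples
#' ring_geometry(17, diameter_A = 340)  # arc ~ 62.8 A
#' @export
ring_geometry <- function(N, diameter_A = NULL, subunit_arc_A = NULL,
                          rung_spacing_A = 32.5, n_rungs = NULL) {
  N <- check_count(N, "N", lower = 3L)
  if (is.null(diameter_A) == is.null(subunit_arc_A)) {
    stop_invalid("give exactly one of `diameter_A` or `subunit_arc_A`.")
  }
  if (is.null(subunit_arc_A)) {
    check_number(diameter_A, "diameter_A")
    subunit_arc_A <- pi * diameter_A / N
  } else {
    check_number(subunit_arc_A, "subunit_arc_A")
    diameter_A <- N * subunit_arc_A / pi
  }
  height_A <- if (is.null(n_rungs)) NA_real_ else {
    n_rungs <- check_count(n_rungs, "n_rungs")
    n_rungs * rung_spacing_A
  }
  tibble(N = N, diameter_A = diameter_A, subunit_arc_A = subunit_arc_A,
         rung_spacing_A = rung_spacing_A,
         n_rungs = if (is.null(n_rungs)) NA_integer_ else n_rungs,
         height_A = height_A)
}

#' Subunit spacing of a C_N ring at a radius
#'
#' @inheritParams ring_geometry
#' @param radius_A Radius at which the spacing is evaluated (Å).
#' @return Arc length per subunit, `2 * pi * radius / N` (Å).
#' @export
ring_subunit_spacing <- function(N, radius_A) {
  N <- check_count(N, "N", lower = 3L)
  check_number(radius_A, "radius_A", lower = 0)
  2 * pi * radius_A / N
}

#' Number of parallel protofilaments across a filament
#'
#' @param filament_width_A Filament width (Å), > 0.
#' @param proto_spacing_A Lateral protofilament spacing (Å), > 0 (32.5 from
#'   the 32-33 Å repeat).
#' @return Integer count, `round(width / spacing)`, at least 1.
#' @examples
#' protofilament_count(122, 32.5)  # 4
#' @export
protofilament_count <- function(filament_width_A, proto_spacing_A = 32.5) {
  check_number(filament_width_A, "filament_width_A")
  check_number(proto_spacing_A, "proto_spacing_A")
  if (filament_width_A <= 0 || proto_spacing_A <= 0) {
    stop_invalid("widths and spacings must be > 0.")
  }
  max(1L, as.integer(round(filament_width_A / proto_spacing_A)))
}
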