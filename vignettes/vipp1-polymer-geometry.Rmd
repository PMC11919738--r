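---
title: "Geometry of Vipp1 polymer lattices: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of Vipp1 polymer lattices: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vippgeom)
```

## The scientific problem

The ESCRT-III-like protein Vipp1 polymerizes into several interconvertible
forms on and off membranes: planar sheets and spiral filaments bound to
supported lipid bilayers, helical filaments in solution, and dome-shaped
rings. All of these are built from the same protofilament of side-by-side
hairpin subunits, so their lattices are geometrically related: a helical
filament is, to a good approximation, a planar lattice rolled onto a
cylinder. `vippgeom` implements that geometry end to end:

* **Real space** (`helical_symmetry()`, `start_family()`,
  `principal_vectors()`): a refined helical symmetry — rise per subunit
  (Å) and twist per subunit (degrees) — generates every *k*-start helix
  family. Connecting each subunit *j* to *j+k* gives an azimuthal step of
  `k * twist` reduced to (−180°, 180°]; the sign of the reduced step gives
  the handedness, and `360 * rise / |step|` is the axial spacing between
  adjacent strands of the family.
* **Reciprocal space** (`layer_lines()`, `symmetry_candidates()`,
  `simulate_power_spectrum()`): the Fourier transform of a helix is
  confined to layer lines at heights `Z = (n * twist/360 + m) / rise` with
  Bessel order *n* (|n| equals the start count of the matching family).
  Given indexed reflections, the linear system is inverted over a grid of
  axial indices *m* to enumerate candidate symmetries, the same logic used
  to seed helical refinement.
* **Unrolling** (`unroll_points()`, `unroll_map()`): cylindrical
  projection at a chosen radius maps the 3D lattice (points or a density
  raster) onto the plane `(r·azimuth, z)`, making helical filaments
  directly comparable with the membrane-bound sheets and spirals imaged by
  AFM.
* **Morphometrics** (`afm_synth`/`afm_measure` function families): a
  physically parameterized generator of AFM-like height images with exact
  ground truth, and a measurement pipeline (FFT ridge periodicity, object
  detection and classification, diameters, widths, heights, growth rates)
  mirroring the study-level quantifications.
* **Curvature limit** (`curvature_model()`, `min_planar_diameter()`,
  `requires_tilt()`): the rigid-ridge model that explains why the central
  rings of spirals cannot stay in the membrane plane.

## Reference symmetries

`vipp1_symmetries()` carries the four refined lattices (rise 2.372, 2.440,
2.155, 2.159 Å; twist −75.860°, −75.835°, 68.507°, 85.495°) with the outer
and lumen radii where printed (24.4/12.7 nm and 21.0/10.5 nm diameters).
Derived from them, and reproduced by the test suite: the 4-start
left-handed family with 43.1 Å axial spacing (printed as the 44 Å pitch),
the 17-start right-handed protofilament direction, the near-axial 21-start
(truncated constructs) and 19-start (full length) families, and the
principal Bessel pairs (−4, 17) and (−5, 14) at the mid-wall radii.

Two conventions matter and are fixed package-wide:

* angles reduce to (−180°, 180°], z-up right-handed frame, positive
  reduced step = right-handed strand;
* lattice vectors are evaluated by default at the mid-wall radius
  `(r_lumen + r_outer)/2`. The principal-vector ordering flips near the
  outer wall, and the mid-wall choice reproduces the indexed Bessel pairs;
  the radius is an explicit argument everywhere, so other choices remain
  one keystroke away. The published cylindrical projection does not state
  its radius; we default to mid-wall for the same reason.

On the "pitch of 44 Å" for the 4-start family: the refined parameters give
an axial inter-strand spacing of 43.13 Å, while 44 Å is the pre-refinement
extraction value (the particle-box overlap). The package reports both
`strand_pitch_A` (rise of one strand per full turn) and `axial_spacing_A`
(pitch divided by the start count) with explicit names, and its tests
compare 43.13 against the printed 44 at the stated 1 Å tolerance.

`k_max` defaults to 25: the visible start count is bounded by
circumference over minimum subunit spacing, about 2π·122 Å / 30 Å for the
widest filament here. Length and step ties break toward smaller *k* at an
absolute tolerance of 1e−9 Å.

## Indexing grid search

`symmetry_candidates()` searches axial indices m ∈ [−6, 6] and accepts
rises in [1, 10] Å and any reduced twist by default; the study does not
print its own grid bounds, so these are the package's choice, wide enough
for plausible subunit packing. Candidates are deduplicated at
(0.005 Å, 0.01°) and ranked by RMS height residual over all reflections;
residuals below solver precision (1e−12) are treated as ties and broken
toward smaller rise, because a coarse sublattice (e.g. the 4-start treated
as a 1-start) reproduces any reflection pair that the finer true lattice
does. Layer-line *amplitudes* are deliberately not modelled — indexing uses
positions only, and amplitude envelopes depend on the unmodelled subunit
shape. `simulate_power_spectrum()` therefore only guarantees peak
*positions* (verified against `layer_lines()` within one Fourier pixel).

## The synthetic AFM generator

The generator renders the study conditions; its defaults are the measured
statistics and are not tuned per analysis:

| quantity | default | role |
|---|---|---|
| ridge period | 54 Å | sheet/spiral surface ridges |
| seam period | 122 Å | merged-filament seams, orthogonal to ridges |
| sheet/filament height | 5.5 nm | membrane height offset |
| filament width | 13.4 ± 0.9 nm | normal law |
| spiral outer diameter | 82.7 ± 37.8 nm, floor 30 nm | truncated normal (below) |
| ring (with spiral) diameter | 37.0 ± 3.9 nm | central rings |
| ring protrusion | 1.0 ± 0.2 nm (default 1.0) | above the spiral plateau |
| standalone ring diameter / height | 35.5 ± 2.9 nm / 9.6 ± 2.2 nm | pre-assembled rings |
| growth velocity | 24 ± 19.6 nm/s, floor 0 | per-filament constant |
| ridge amplitude | 0.3 nm | measurable above the 0.1 nm noise |
| height noise | 0.1 nm SD, Gaussian | instrument noise proxy |

Choices the data do not dictate, made once:

* **Truncated laws are moment-matched.** The reported means and SDs are
  sample moments of physically bounded measurements. Rejection-truncating
  a Normal(82.7, 37.8) at 30 nm would shift its realized mean to ~89 nm
  and a Normal(24, 19.6) at 0 to ~28 nm, so the generator instead solves
  for the underlying normal whose truncated law has exactly the configured
  mean and SD. The distribution family itself (the diameter SD is nearly
  half the mean, hinting at skew) is a generator assumption.
* **Spiral geometry.** Archimedean arms with turn spacing = width + 6 nm
  membrane gap, so neighbouring turns stay resolvable at 2 nm pixels; the
  outermost turn continues at constant radius for 1.2π so the rendered
  outer extent equals the drawn diameter in every direction, as in mature
  spirals whose outer turn wraps the perimeter. A consequence embraced by
  the classifier: such spirals are topologically holed, because the
  closing turn pinches the inter-turn channel.
* **Rings.** Central rings abut the innermost arm (one connected object)
  and are drawn from the 37 nm law, shrunk when a small spiral cannot
  contain them; standalone rings get a 10 nm wall so the lumen stays
  resolvable.
* **Growth.** Filaments elongate from one tip at per-filament constant
  velocities, 10 frames at 0.25 s; fields are sized so filaments never
  collide at their final lengths.
* **Random streams.** Each object class draws from its own derived
  sub-seed, so adding rings does not perturb the spiral draws
  (bit-reproducibility per seed is tested).

Not simulated, hence untested against real data: tip convolution and
finite tip radius (all real AFM widths are tip-broadened), scanner drift
and line noise, tapping-phase contrast, filament flexibility, and
vendor file formats. Passing recovery tests therefore demonstrate that the
*pipeline* is unbiased on idealized rasters of the right scales — not that
it would match a real instrument without tip deconvolution.

## Measurement conventions

* Background = mode of the height histogram at 0.1 nm bins (the membrane
  dominates every preset); objects are pixels more than 2 nm above it.
* `ridge_period()` mean-subtracts and Hann-windows the masked region,
  takes the strongest amplitude peak in the 2–20 nm period band, and
  refines it by parabolic log-amplitude interpolation (sub-pixel). A peak
  must exceed 3× the median amplitude at its own frequency *and* 2× the
  99th percentile of the band; otherwise `NA` with a reason attribute is
  returned — the no-periodicity signal, distinct from an error.
* Classification: a topological hole whose enclosed region is itself
  compact (hole solidity ≥ 0.9) marks a ring; large high-solidity plateaus
  (≥ 4·10⁴ nm², solidity ≥ 0.7) are sheets; objects whose outer pixels
  cover ≥ 55% of 5° angular bins about the centroid (or that contain a
  protruding central ring) are spirals; the rest are filaments. A
  turns-based spiral definition is not usable here: the smallest spirals
  the default diameter law produces (30–40 nm at 13.4 nm width) cannot
  complete 1.5 turns, yet they are spirals by provenance and must be
  counted as such.
* Diameter = minimal enclosing circle (exact, Welzl on the convex hull) of
  the mask, an outer dimension; the printed spiral diameters do not define
  their convention, so this one is documented instead.
* Width = 2× the mean medial-axis value of the Euclidean distance map,
  minus a quarter-pixel correction calibrated on noiseless ribbons of
  known width (the distance map measures to background pixel centres while
  medial pixels sit off the true centerline).
* Filament length = `(area − π·width²/4) / width`, exact for a
  constant-width ribbon with rounded caps; the cap term cancels in length
  differences, which is what growth velocities use. This replaces
  skeleton-arc-length, which is noisier at 2 nm pixels, and matches it in
  expectation for straight or gently curved filaments.
* Ring protrusion = mean height of the central elevated annulus (pixels
  more than 0.4 nm above the object plateau, compact and central) minus
  the mean height of the remaining spiral pixels.

## The planar curvature limit

Ridges are treated as rigid elements whose spacing is relaxed (54 Å) at a
reference line and scales with local radius across a bend of centerline
radius R and width w: `s_inner = s0(R − w/2)/R`, `s_outer = s0(R + w/2)/R`.
With the observed compression/stretch bounds (~41 Å, ~61 Å) the binding
constraint is `R ≥ s0 (w/2) / (s_max − s0)`, giving a minimum planar
centerline diameter of ≈ 103.4 nm at the 13.4 nm width — far above the
37.0 nm central rings, which must therefore tilt out of plane
(`requires_tilt()`, with the boundary counted as feasible). The default
reference line is the centerline (symmetric treatment of both bounds); the
inner-edge-relaxed alternative is exposed via `reference = "inner"`.
Because the printed bounds carry "~", `min_planar_diameter_sensitivity()`
reports the limit over a ±2 Å grid on each bound rather than resolving the
ambiguity. The brute-force cross-check scans radii at 0.02 Å steps. The
relation between the 1.0 nm ring protrusion and a tilt angle is not
quantified in the source material, and no tilt-angle operation is offered.

## Spiral fitting

`fit_spiral()` fits `r = a + b·θ` (Archimedean) or `r = a·exp(b·θ)`
(exponential) in polar coordinates about a centre optimized jointly with
the shape parameters: Nelder-Mead over the centre (reltol 1e−12 plus two
restarts, which polish noiseless fits to machine precision) with the shape
fit closed-form (linear) or Gauss-Newton (exponential, log-linear
initialized) inside. θ is unwrapped along the trace order and the
orientation normalized so θ increases; traces spanning under 1.5 turns or
with more than 0.5 rad of total backward angular motion (beyond noise
jitter) raise typed errors. `"auto"` selection uses AIC under Gaussian
residuals; both models have the same parameter count, so this reduces to
comparing residuals, stated explicitly for reproducibility.

## Numerical and testing choices

Problem sizes in the test suite were chosen to exercise every code path at
desk scale: 1,000 random symmetries for the brute-force principal-vector
and layer-line duality properties, 200 indexing round-trips, 100 simulated
traces per spiral form (σ = 0.5 nm), a 100-spiral field for
detection/recovery, ten growth series for the velocity mean (the
per-filament velocity law is so wide that a single 11-filament series
pins its own mean to only ±25%), and 64–96 voxel maps for unrolling. File
formats: MRC modes 0/1/2 with header-derived per-axis voxel sizes; AFM
rasters as 32-bit float TIFF min-max normalized to [0, 1] with the offset
and scale recorded in the JSON sidecar (so heights round-trip at float32
precision, the most such a file can preserve); CSV/JSON fields carry unit
suffixes (`_A`, `_nm`, `_invA`, `_deg`) because the source material mixes
Å and nm.

## Known limitations

* Bessel amplitude envelopes and radius-dependent Bessel maxima are out of
  scope, so Bessel orders cannot be assigned automatically from radial
  peak positions — only from the real-space start families.
* The classifier thresholds (solidity, angular coverage, hole solidity)
  are calibrated on the package's own generator and are not expected to
  transfer to real AFM data without adjustment.
* Atomic coordinates, map alignment/refinement and membrane mechanics
  (bending energies, abscission forces) are deliberately absent.
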