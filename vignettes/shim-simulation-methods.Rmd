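---
title: "Simulating multi-coil and spherical-harmonic B0 shimming for whole-brain MRSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-coil and spherical-harmonic B0 shimming for whole-brain MRSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unicshim)
```

## The problem

Spatial variation of the scanner's static field B0 shifts the local proton
resonance frequency. For 3D MR spectroscopic imaging (MRSI) this is the
binding constraint: the frequency spread *within* each MRSI voxel broadens
its spectral lines, and voxels whose modelled linewidth exceeds a usability
threshold yield no quantifiable spectra. The worst offenders are the
air–tissue interfaces of the frontal sinus, the ear canals and the skull
base, which imprint strong, spatially high-order field perturbations on the
prefrontal cortex (PFC) and the temporal lobes.

`unicshim` simulates *static whole-brain shimming* of measured or synthetic
off-resonance field maps with six methods and scores each by two figures of
merit:

* **Homogeneity** — the population standard deviation (SD) of the
  off-resonance frequency over the brain mask, before and after shimming.
* **MRSI brain coverage** — the percentage of in-brain MRSI voxels whose
  modelled linewidth is below threshold.

The six methods are spherical-harmonic (SH) shims of order 2 (the standard
scanner configuration) through 5 (theoretical benchmarks), a 32-channel
helmet of 9.5 cm shim–RF shared loops, and a 51-channel layout that adds 24
small two-turn loops over the forehead and around each ear to 27 large
helmet loops.

## Shim model

For a brain mask with `n` voxels and a method with `p` channels, the basis
matrix `A` (`n x p`) holds each channel's off-resonance field per unit drive:
Hz per ampere for a coil loop (Biot–Savart), Hz per unit coefficient for an
SH term. With the measured field `f` (Hz) the shim currents/coefficients
solve the box-constrained least squares problem

    minimise ||f + A c||^2   subject to   l <= c <= u,

the same mean-square objective a scanner's shim calibration minimises. Coil
channels are bounded at ±3.0 A; SH coefficients are unbounded (they model
ideal shim hardware). A global frequency term is always available and
unbounded — for SH methods as the degree-0 column, for coil methods as an
explicit appended constant — mirroring the scanner's center-frequency
adjustment. The residual `f + A c` is the shimmed field map; every
downstream metric is computed from it.

The solver is an exact dual active-set quadratic program on the normal
equations (`quadprog`), with a relative ridge of `1e-10` on the Gram matrix
so that redundant channel sets (e.g. overlapping loops) remain well posed;
among exactly optimal coefficient sets this selects an essentially
minimum-norm one. Optimality of every solve can be audited post hoc with
`kkt_check()`: interior channels must have zero objective gradient, channels
at a bound must have the gradient pointing outward.

Because the SH bases are *nested* (the degree-`k` columns are a prefix of
the degree-`k+1` basis) the residual SD is non-increasing in SH order on any
input, exactly — a structural invariant the test suite asserts.

## Coil fields

Loop fields are computed from the Biot–Savart law for a polygonal
discretisation of each circular loop (default 256 chords, midpoint rule;
the `n^-2` discretisation error is ~1e-4 relative at that setting), summed
over turns, and converted to frequency with the proton gyromagnetic ratio
42.577 MHz/T. Only the z-component of B matters for off-resonance (the
standard MR approximation). An independent closed-form implementation via
complete elliptic integrals (`loop_bz_analytic()`) serves as the oracle for
the polygonal kernel in the tests; the two agree to better than 0.1% at
randomized points 2–15 cm from the wire.

The helmet is a 115 mm spherical dome over a 60 mm cylindrical skirt. Large
loops are placed by a deterministic golden-angle area-uniform rule; the
51-channel layout adds a 2 × 4 forehead grid of 5 cm two-turn loops on the
shell and a ring of eight 4 cm two-turn loops per ear. The ear rings sit on
sagittal earmuff insets at |x| = 82 mm rather than on the shell: loops meant
to sit "in the ear cavity" are against the head in practice, and placing
them 55 mm away on the shell would forfeit exactly the targeted-shimming
behaviour the layout exists to exercise. All geometry serialises to JSON, so
measured coordinates can replace these documented approximations without
code changes.

## Linewidth model and coverage

Each MRSI voxel's linewidth is modelled as

    linewidth = baseline + SD(in-mask field-map pixels in the voxel)

with a 9 Hz baseline lumping the T2 term `1/(pi T2)` and microscopic
susceptibility broadening, and an 18 Hz usability threshold (strict `<`),
the standard water-linewidth criterion. At the native 2.4 × 2.4 × 2 mm grid
a 12 × 12 × 10 mm (1.44 cc) MRSI voxel contains a 5 × 5 × 5 block of 125
field-map pixels; a 4.8 × 4.8 × 4 mm request realises 0.092 cc.

Numerical conventions, chosen once and applied everywhere:

* All SDs are population SDs (denominator `n`).
* Blocks tile from the volume origin; trailing partial blocks are kept.
* A block is a *brain voxel* iff more than 50% of its pixels are in-mask;
  its SD uses in-mask pixels only. ROI membership uses the same majority
  rule on the in-mask pixels.
* The threshold comparison is strict (`linewidth < 18` Hz), so a block with
  pixel SD exactly 9 Hz is unusable.

Coverage is `100 · usable / brain voxels`, whole-brain or within an ROI.
Because the metric is SD-based it is invariant to any global frequency
offset, which is why the f0 handling above cannot bias it.

## The synthetic cohort generator

The study design calls for 24 subjects of whole-brain dual-echo GRE field
maps (2.4 × 2.4 × 2 mm voxels, 214 × 250 × 120 mm FOV, 3 T). Since measured
maps cannot be redistributed with the package, `generate_cohort()` produces
seeded synthetic subjects that emulate their *statistical structure*:

* **Anatomy** — a brain-shaped ellipsoid (default semiaxes 70 × 85 × 55 mm,
  ~1.4 L, chosen to fit the stated FOV with margin).
* **Air spaces** — sphere *clusters* per anatomical site: a three-lobe
  frontal sinus, ear canal plus mastoid cells per side, and a
  sphenoid/oral/nasopharyngeal skull-base row. Each sphere contributes the
  external Lorentz-sphere dipole field
  `f0 (Δχ/3) (a/r)^3 (3 cos²θ − 1)` with Δχ(air−tissue) = 9.4 ppm at 3 T.
  Clusters of spheres, mostly extracranial, give the broad moderately steep
  fields measured maps show, rather than the sharp shell of one small
  sphere.
* **Mask margin** — the mask excludes a 6 mm shell around each cavity:
  air is separated from brain by bone and CSF, and brain extraction drops
  the signal-void interface zone, so real field maps never sample the
  immediate interface. Without this margin the field contains voxel-scale
  spikes that no shim can address and that drown every method comparison.
* **Smooth background** — a degree-2 polynomial (coefficients in Hz at
  10 cm) for the residual low-order inhomogeneity left by the magnet.
* **High-order background** — a seeded random solid-harmonic field of
  degrees 3–5 (RMS 10/8/6 Hz over the brain). Measured maps retain broad
  high-order structure from distal susceptibility sources (neck, torso),
  distributed tissue heterogeneity and scanner-shim residuals; this term is
  what second-order shimming demonstrably cannot remove, and without it a
  1.44 cc coverage metric cannot separate the methods at all.
* **Noise** — 2 Hz i.i.d. Gaussian per voxel.
* **Between-subject variability** — seeded jitter of cavity positions
  (SD 3 mm), radii (SD 0.8 mm), ellipsoid semiaxes (SD 3 mm) and polynomial
  coefficients (SD 3 Hz); the high-order background redraws per subject.

All randomness flows from explicit seeds; the same master seed reproduces a
cohort bit for bit. The default cohort's pre-shim whole-brain SD lands at
40–50 Hz, within the 20–80 Hz band typical of unshimmed 3 T brain maps.
The PFC and MTL+temporal-pole ROIs are geometric boxes anchored to the
cavity-cluster centroids (atlas registration is out of scope), so regional
analyses stress the same areas the air cavities disturb.

**What the generator does not emulate:** real gyral/tissue anatomy, the
actual spatial spectrum of measured sinus fields, physiological field
fluctuations, and the unpublished measured coil coordinates. Passing the
cohort-level tests therefore demonstrates that the *pipeline* reproduces the
qualitative method ordering under controlled, realistic-by-construction
conditions; it does not re-derive the study's numerical tables, which
require the original field maps.

## Study sizes and runtime

The default study (`run_study()`) processes 24 subjects × 6 methods × 2
resolutions at the native 2.4 × 2.4 × 2 mm grid (~115,000 brain voxels per
subject). The Biot–Savart kernel is compiled (Rcpp), which keeps a full
cohort run at roughly 5–6 minutes on one CPU; unit tests use a 6 × 6 × 5 mm
grid of the same anatomy so each check runs in well under a second.

## Design choices that were genuinely open

* **SD convention** — population SD throughout; with 125-pixel blocks the
  sample/population difference is negligible, but determinism requires one
  choice.
* **Paired pairwise tests** — every subject is shimmed by every method, so
  the pairwise comparisons after the one-way ANOVA default to paired
  t-tests with Bonferroni multiplier `choose(k, 2)`; the unpaired variant
  is available (`paired = FALSE`).
* **Phase conversion** — `phase_diff_to_hz()` wraps the echo-pair phase
  difference into `[-π, π)`; unwrapping beyond that single wrap is out of
  scope and inputs are assumed alias-free (±203 Hz at ΔTE = 2.46 ms).
* **Expansion center** — SH bases expand about the brain-mask centroid, the
  natural shim isocenter; columns are RMS-normalised over the mask purely
  for conditioning (solutions are invariant to column scaling when
  coefficients are unbounded).
* **27 large UNIC loops** — placed by the same even rule as the 32-loop
  helmet but independently; the alternative reading (reusing 27 of the 32
  shared-loop positions) can be built by subsetting `layout_ipres32()` and
  saving the result as a JSON layout.
* **Degenerate inputs** — empty masks, infeasible bounds (zero current must
  always be feasible), non-finite fields, loops threading the brain, and
  ROIs that miss every brain voxel are all hard errors, not warnings.

## Known limitations

Linewidth is a two-term model, not a spectral simulation; coverage at very
coarse grids degenerates (a 1-pixel block has zero SD by construction); the
coil model ignores wire cross-section, eddy currents, inductive coupling
and amplifier dynamics; and the cohort statistics assume the complete
subject × method grid produced by a successful run.
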