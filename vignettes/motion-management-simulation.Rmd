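---
title: "Simulating ITV versus tumor-tracking SBRT with 4-D dose accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ITV versus tumor-tracking SBRT with 4-D dose accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pancreatic tumors move with respiration — typically 1–11 mm peak-to-peak,
largest along the superior–inferior axis — and sit immediately adjacent to
radio-sensitive organs, above all the duodenum. Stereotactic body
radiotherapy (SBRT, here 5 × 5 Gy) must manage that motion. Two standard
strategies are compared throughout this package:

* **ITV concept** (motion encompassing): the gross tumor volume (GTV) is
  contoured on every breathing phase of a respiration-resolved image set;
  the union of all phase GTVs — the *motion envelope* — is the internal
  target volume (ITV), which receives a 5 mm setup margin to form
  `PTV_itv`. The whole envelope is irradiated on the time-averaged
  anatomy.
* **Tumor tracking**: the GTV of one reference ("contouring") phase — the
  phase nearest the time-averaged tumor position, i.e. mid-ventilation —
  receives the same 5 mm margin (`PTV_track`), and the beam isocenter
  follows the tumor during delivery. Tracking is modelled as perfect
  (zero latency and zero tracking error); the 5 mm margin is what absorbs
  residual uncertainty.

Because a static ("3-D") dose distribution does not describe what a
*moving* tumor accumulates, both arms are additionally evaluated with a
**4-D dose calculation**: each treatment arc is cut into angular segments,
the segments are assigned to the breathing phases during which they are
delivered, per-phase sub-doses are computed (with the isocenter shifted to
the phase's tumor centre-of-volume in the tracking arm), warped to the
reference phase along known displacement fields, and summed.

Patient images are not available to a desk-scale reimplementation, so two
substitutions define the package's scope:

1. **Synthetic 4-D phantoms** stand in for patient 4DCTs
   (`make_phantom()`): ground-truth displacement fields replace deformable
   image registration.
2. A **surrogate dose engine** replaces the commercial inverse-optimized
   VMAT dose calculation (`compute_arc_dose()`).

What survives these substitutions — and is reproduced exactly — is the
published cohort arithmetic: the bundled 12-patient table of motion
amplitudes and PTV sizes (`load_table1()`), every summary statistic
derivable from it, the reduction-vs-motion regression, and the paired
nonparametric inference. What does not survive is any *absolute* patient
dose value; those depend on the unavailable images and are out of scope.

## The phantom

`phantom_config()` describes a ~128 mm cube at 2 mm isotropic voxels
(64³). The body is a z-extruded elliptic cylinder of water-equivalent
density 1 (air 0); a GTV ellipsoid sits at the pancreatic head position
with a duodenal tube at a configurable lateral gap, plus stomach, bowel,
liver, kidneys and a static spinal cord.

Breathing is a single-frequency cosine, `s(t) = (1 - cos 2πt/T)/2`,
sampled at the midpoints of `n_phases = 10` equal-duration bins
(`make_breathing_trace()`); phase-sorted binning is assumed. The phantom
rescales the sampled trace to span exactly [0, 1] before multiplying by
the configured peak-to-peak amplitudes — the raw 10-bin midpoint samples
span only [0.025, 0.975], and without rescaling every generated amplitude
would be biased 5% low. All abdominal organs translate rigidly with the
same displacement (`rigid` mode); `rigid_plus_local` adds a smooth
Gaussian-windowed superior–inferior perturbation near the diaphragm to
exercise the deformable warping code.

The reference phase defaults to the bin whose trace value is nearest the
time average — the mid-ventilation choice. Reference-phase structures are
voxelized analytically; the other phases are produced by propagating the
reference masks along the ground-truth fields with nearest-neighbour
resampling. This mirrors how clinical structures are propagated by
registration, and it makes propagation consistency exact: re-applying
`propagate_mask()` reproduces a stored phase mask identically (the Dice
test would be vacuous were phase masks voxelized independently — no
resampling scheme reaches Dice 0.99 against an independently voxelized
2 mm structure under sub-voxel shifts; we measured ≈ 0.87 for
nearest-neighbour and ≈ 0.96 for interpolated-threshold resampling). The
price is that centre-of-volume trajectories are quantized to the voxel
lattice, so configured amplitudes are recovered within one voxel rather
than exactly.

With `jitter_mm > 0`, organ centres (and the GTV size) are perturbed
from a seeded RNG so a virtual cohort has anatomical variety; the global
RNG state is saved and restored.

The generator does **not** model CT Hounsfield realism, image noise,
irregular breathing, baseline drift, or inter-fraction change. Passing
tests therefore demonstrate correctness of the geometric/dosimetric
machinery under idealized periodic motion, not performance on real
patient images.

## The surrogate dose engine

`beam_model()` has two physical parameters: an effective linear
attenuation `mu = 0.004 mm^-1` (a 10 MV-class beam in water) and a
Gaussian penumbra `sigma = 3 mm`. For each of 144 sampled gantry angles
(two full 360° arcs, 5° steps, opposite rotation directions, collimator
5°/355° kept as metadata), the aperture is the beam's-eye-view (BEV)
projection of the PTV (`bev_aperture()`); dose is

> weight × exp(−mu × radiological depth) × T(lateral position),

where T is the aperture indicator convolved with the penumbra Gaussian,
implemented as a normal CDF of the signed Euclidean distance to the
aperture edge. Radiological depth is the water-equivalent path length
from the body surface; because the gantry rotates in the axial plane,
rays never cross axial slices and depth reduces to per-slice 2-D
integrals (computed by cumulative sums on a beam-aligned lattice and
cached per angle in `make_dose_engine()`).

Monitor units are uniform per degree; plans are normalized so that the
PTV voxel at rank ⌈0.95 n⌉ of the descending dose sort receives exactly
25 Gy (`normalize_prescription()`). This order-statistic rule guarantees
"≥ 95% of the PTV at prescription" *by construction*; the interpolated
D95 agrees with 25 Gy to well under 0.01 Gy. With a zero aperture margin
the PTV surface sits mid-penumbra, so normalization escalates the target
interior to ~130% of prescription — the intended behaviour of a
peripheral 60%-isodose prescription (maximum allowed 41.5 Gy, reported
and gated, never clipped).

The simultaneous-integrated-protection (SIP) logic
(`apply_sip_adjustment()`) emulates risk-adapted optimization with a
deterministic heuristic: while a hard objective fails — an organ-at-risk
(OAR) limit (cord Dmax < 25 Gy; bowel/duodenum/stomach Dmax < 27.5 Gy;
kidney Dmean < 10 Gy), or the near-maximum D0.1cc of a PTV∩OAR overlap
above the 27.5 Gy window ceiling — the BEV projection of the overlap
region is subtracted from the apertures of the angles contributing most
to the excess (at most 20 iterations, ~15% of angles per iteration,
incremental dose updates), and the plan is renormalized. The 27.5 Gy
*minimum* aimed at in the non-overlapping PTV is reported as a non-gating
row: with the prescription pinned at D95(PTV) = 25 Gy the PTV rim always
sits near 25 Gy, so a strict 27.5 Gy minimum is an optimizer aspiration,
not a satisfiable constraint — exactly why hard envelope-arm plans end
with a *compromise* (overlap coverage dropping into the 80–90% range)
rather than a feasible solution. `objectives_met` gates on the hard set:
OAR limits, PTV coverage, the overlap window, and the 41.5 Gy ceiling.

This engine is declared, not validated, physics: no inverse optimization,
no MLC sequencing, no heterogeneity correction beyond density path
scaling, no Monte Carlo. The claims under test — PTV geometry, motion
robustness, directional OAR sparing — are geometric and motion-driven,
which is what the surrogate preserves.

## 4-D dose accumulation

`segment_arc_by_phase()` cuts an arc at every phase transition under
constant gantry speed (default 3°/s, i.e. 120 s per arc; breathing period
4 s) and uniform MU per degree; shares are exact fractions, so total MU
is conserved to 1e-12 and long deliveries approach 1/n per phase.
`accumulate_4d()` evaluates every (angle, phase) combination that
receives monitor units, shifting apertures by the phase's tumor
displacement in tracking mode, warps each phase dose to the reference
phase by pull-back trilinear interpolation (`warp_dose_to_reference()`;
dose interpolation without mass rescaling, the standard deformable
dose-summation approximation), and sums. Five identical fractions start
at breathing phases 1, 3, 5, 7, 9 to average interplay; a zero
displacement field short-circuits to an exact identity so zero-motion
accumulation is bitwise the static dose.

3-D metrics are evaluated on each arm's planning structures (ITV /
reference GTV as target); 4-D metrics are evaluated on reference-phase
structures with the GTV as target for both arms, so accumulated doses are
compared on identical anatomy (`summarize_metrics()`).

One stated module property was recast: under the conformal surrogate the
*absolute* accumulated GTV dose of the envelope arm can exceed the
tracking arm's, because normalizing a larger PTV places the D95 point
deeper in the penumbra and runs the interior hotter — in the published
study the smaller tracking PTV escalated more because an inverse
optimizer was driving it. The surrogate-valid form of the property, and
what the tests assert, is motion *robustness*: accumulating over the
breathing cycle degrades tracking-arm GTV coverage no more than
envelope-arm coverage, and perfect tracking under rigid motion preserves
the GTV dose to within 2% of prescription.

## Dose-volume metrics

`dose_at_volume_percent()` uses descending-sort rank interpolation
(`DxX` at fractional rank x·n/100, linear between order statistics), not
nearest-bin lookup, so 3-D and 4-D values are directly comparable;
`dose_at_absolute_volume()` applies the same rule at rank cc/voxel-volume
(with 2 mm voxels, 0.008 cm³, the 0.1 cm³ boundary is sub-voxel). Dmin
and Dmax are true voxel extrema. `cumulative_dvh()` defaults to 0.05 Gy
bins. The bin width and interpolation rule are this package's decisions;
they are stated here because published DVH parameters rarely specify
them.

## Statistics

`wilcoxon_signed_rank()` drops zero differences, midranks ties, and for
n ≤ 20 computes the exact two-sided p-value from the distribution of the
rank sum over all 2ⁿ sign assignments (dynamic programming over doubled
ranks — identical to complete enumeration, which the tests verify on 200
random cases). `spearman_rho()` is Pearson correlation of midranks with
the t-approximation p-value (an exact permutation option exists for
n ≤ 8). `linear_fit()` is ordinary least squares via `stats::lm`.

Two fixture conventions matter. First, the signed reduction
(−100·(V_itv − V_track)/V_itv) is used for the regression and
correlation, matching the plotted axis; prose summaries use absolute
values. Second, the statistics use the cohort table's *printed* 3-D
motion column (1 d.p.): the published slope (−2.28), ρ (−0.46) and
p (0.131) reproduce exactly only from the printed column — recomputing
3-D motion from the per-axis amplitudes gives slope −2.27 and ρ −0.50.
The per-axis columns remain authoritative for validation: `load_table1()`
recomputes the 3-D motion and requires agreement with the printed column
within 0.15 mm (the worst printed-vs-recomputed discrepancy, patient 9,
is 0.10 mm — a rounding artefact of the 1 d.p. inputs). Quartiles use
linear interpolation between order statistics (type 7); the median is the
midpoint of the two central order statistics; SDs are sample SDs (n−1).
No multiple-testing correction is applied, matching the study design.

## Geometry conventions and numerical choices

* Axes: x = left–right, y = anterior–posterior, z = superior–inferior;
  mm; voxel-centre sampling; 1-based indices (R convention).
* Margin expansion (`expand_margin()`): a voxel joins the expanded
  structure when its centre lies within the margin of the input,
  measured to occupied voxel centres with a **quarter-voxel surface
  allowance** (ties included). A strict centre-to-centre rule undersizes
  a 10 mm → 15 mm spherical expansion by ~4% on a 1 mm grid because the
  true surface lies beyond the outermost centres; the allowance brings it
  to ~1% while preserving margin-0 identity and monotonicity.
* Opposed gantry angles share one BEV frame (the beam line, angle
  mod 180°), giving exact parallel-beam aperture symmetry; attenuation
  still distinguishes the two directions.
* Tumor density defaults to 1.0 (no contrast) per the water-equivalent
  body; `gtv_density` adds contrast when phase-averaging behaviour
  itself is under study, at the cost of per-slice depth recomputation.
* Degenerate inputs raise typed errors (`empty-structure`,
  `invalid-config`, `geometry`, `domain`, `normalization`,
  `undefined-test`), asserted in the test suite.

## Problem sizes

The study geometry is 12 virtual patients on 64³ grids with 10 phases and
two 5°-sampled arcs; the full cohort (both arms, SIP, both 4-D
accumulations) runs in about 5 minutes on one CPU. Unit tests exercise
the same code paths on 24³–48³ grids with proportionally scaled organs.
The directional duodenum-sparing property uses 20 seeded virtual patients
at 64³ with ≥ 5 mm superior–inferior motion. These sizes are the
package's chosen study conditions; the phantom amplitudes of the virtual
cohort are taken per-patient from the bundled reference table.

## Known limitations

* The dose engine is a two-parameter surrogate; absolute OAR/target dose
  levels are not comparable to clinical plans, only paired contrasts
  between arms under identical geometry are meaningful.
* Perfect tracking overstates any real system; latency and prediction
  error are absorbed only notionally by the 5 mm margin.
* Periodic single-frequency breathing ignores cycle-to-cycle variability,
  which in reality degrades both arms (and envelope definitions).
* The virtual cohort's PTV volumes are smaller than the reference
  cohort's (desk-scale organs); volume-dependent effects do not
  extrapolate.
* `rigid_plus_local` deformation is a smooth toy perturbation for
  exercising warping code, not a tissue-mechanical model.
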