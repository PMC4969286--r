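---
title: "Reciprocity-based TES targeting: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocity-based TES targeting: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesplan)
```

`tesplan` plans multi-electrode transcranial electrical stimulation (TES)
montages by the reciprocity principle and audits their dose. This vignette
explains the models it uses, the choices that were genuinely open and how
they were made, and what the validation on synthetic phantoms does and does
not establish.

## The forward model

Current flow in the head at stimulation frequencies is quasi-static: the
potential obeys ∇·(σ∇φ) = −s, with conductivity σ from a seven-tissue
table (S/m): eyeball 1.5, scalp 0.44, skull 0.018, CSF 1.79, gray matter
0.25, white matter 0.35, air 0. These are standard literature values; skull
is the controlling resistance (scalp/skull contrast ≈ 24:1) and CSF the
dominant shunt.

The solver discretizes on the voxel grid of the phantom with a 7-point
finite-difference stencil. The conductance across each voxel face is the
harmonic mean of the two adjacent voxel conductivities times the face
geometry factor — the harmonic mean is exact for series resistances in
one dimension and makes discrete flux continuous across tissue interfaces.
Air voxels carry no unknowns, so every conductor–air face is automatically
a zero-flux (Neumann) boundary. The operator is symmetric positive
semidefinite with a constant null vector; solves fix one reference node
(keeping the reduced system positive definite), then shift the result to
average reference over conducting voxels. The linear solves use
Jacobi-preconditioned conjugate gradients at a relative-residual tolerance
of 1e-8 by default — well below the discretization error at any spacing a
desk machine can afford, so the tolerance never dominates results.

Electrodes are modeled as point sources at the nearest scalp-surface voxel.
The 1 cm² contact area enters only dosimetry (current density per
electrode), not the field model: a contact-impedance model would add
parameters the planning results are insensitive to, because montage
construction depends only on voltage *ratios*.

### Phantoms and their resolution

Phantoms are concentric-shell spheres voxelized by a voxel-center
point-in-region test (no partial-volume mixing), matching what the simple
stencil assumes. The default head is gray matter to 78 mm, CSF to 80 mm,
skull to 85 mm, scalp to 92 mm. Note the CSF layer is 2 mm thick: at the
default working spacings (4 mm for quick runs, 2 mm for careful ones) it is
at or below grid resolution, which is true of real heads and real solvers
alike and is the main accuracy limit discussed under *Validation*.

## Cortical patches and their normals

Targets are ~1 cm²-scale parcels of a triangulated cortical surface. The
parceller takes k = round(area/target) seeds by farthest-point sampling
(the first seed at the mesh's most extremal triangle, so small exact
tilings land on corners), assigns every triangle to its nearest seed,
reconnects any stray components, and runs a boundary rebalancing sweep
(repeated up to three times or until no move reduces the squared area
deviation) so that patch areas concentrate around the target. Patch
normals average the member vertex normals weighted by incident area —
robust to uneven triangulation; an unweighted mean is available by flag.
Patches that fold so strongly that their normals nearly cancel are flagged
degenerate and fall back to the largest triangle's face normal; targeting
through such a patch is not meaningful and the flag is the warning.

Synthetic cortices are icospheres and sinusoidally perturbed
("wavy-gyrus") spheres; the latter exercises opposing normals.

## Reciprocity targeting

The lead-field matrix L (electrodes × patches) holds the average-referenced
scalp voltage per unit dipole moment along each patch normal. Reciprocity
lets one build it column-free: one forward solve per electrode (unit
current against a fixed reference electrode), then the entry is the
directional derivative of that electrode's potential field at the patch
centroid. With hundreds of electrodes and thousands of patches this is the
only practical route, and it is exact in the discrete sense because the
stencil matrix is symmetric.

Montage construction for a target patch:

1. **Project**: take the lead-field column of the target (its scalp
   voltage topography), negated for cortical-surface-cathodal polarity.
2. **Select**: the N electrodes with the largest positive voltages become
   sources, the M with the largest-magnitude negative voltages sinks
   (ties break to the lower electrode index; the choice is arbitrary and
   documented).
3. **Weight**: top source +1, top sink −1, others proportional; multiply
   by the per-channel cap (200 µA).
4. **Balance**: scale the heavier side down so the signed currents sum to
   exactly zero.
5. **Cap**: if the one-sided total exceeds min(requested, 2 mA), scale
   everything down by that ratio. Both steps only shrink magnitudes, so
   the per-channel cap can never be re-violated.

"Total current" throughout means the one-sided (anodal) sum — with eight
200 µA channels the ceiling is 1.6 mA, consistent with quoted cohort-mean
totals near 1.2 mA.

### Sign convention

The package reports the signed normal current density along the **anodal
direction**: from the scalp into the cortex, i.e. against the outward patch
normal. Positive values mean cortical-surface-anodal current at that patch.
This is the convention under which (i) the anodal projection is the plain
lead-field column of the outward-normal dipole, and (ii) a montage built
from it yields a positive target dose. (With the outward normal instead,
discrete reciprocity gives target n·J = −σ·(currents · lead-field column),
and one of the two statements would flip sign.) It is also the
physiologically natural sign: inward current is what flows under an anode.

### Sham

The matched placebo montage keeps both active clusters but drives only two
local pairs: in each cluster, the electrode that carried the least current
is paired with its nearest neighbour in the array (Euclidean distance;
array topology is not defined for an arbitrary electrode set), 100 µA per
pair, 200 µA total positive. Current then loops shallowly under the scalp,
preserving sensation while sparing the target. If the nearest neighbour
already carries opposite-side active current, the next-nearest free
electrode is used with a warning.

## Dosimetry

Injection time is duty-cycle arithmetic: continuous waveforms inject for
the whole session; rectangular pulse trains for duration × pulse/(pulse +
inter-pulse interval); a truncated sham train for n_pulses × pulse. Charge
is current × injection time, except slow-oscillatory DC, where the
sinusoid runs from 0 to the peak and the time-averaged current is half the
peak — a stated convention of this package, chosen because it reproduces
published charge figures from their printed peak currents and durations.
Published pulse frequencies are treated as rounded; presets store pulse
width and inter-pulse interval as ground truth (0.5 s + 0.05 s is a 1.818…
Hz train, printed as "1.8 Hz"). Quoted current densities use half-up
rounding to two decimals (1.16 mA over eight 1 cm² electrodes → 0.145 →
0.15 mA/cm²), with a one-ulp guard because exact decimal halves are not
binary-representable.

## MEP statistics and the synthetic cohort

Excitability readouts are motor evoked potentials: blocks of 12 TMS pulses
summarized by dropping exactly one minimum and one maximum (first
occurrence on ties) and averaging the remaining 10; 10-trial baseline
blocks average untrimmed. Session ratios divide interval means by the
baseline mean; the overall ratio averages the nine post-stimulation
intervals (0–30 min in 5-min steps, then 60 and 90), with early (≤30) and
late (≥60) groupings. Condition contrasts are classical paired one-tailed
t-tests against placebo — one-tailed because the directional hypothesis
(inhibition) is fixed a priori. Whether the "overall" contrast should
average intervals per participant before the paired test or pool
interval-level values is ambiguous; this package averages first, the
conservative reading that keeps n = participants. Responder counts are
compared to published proportions by exact binomial upper-tail sums; the
null proportions default to the exact published fractions (22/53, 0.26),
with rounded variants available — conclusions do not change either way.

The cohort generator draws, per participant and condition, a baseline from
Normal(0.97, 0.35) mV truncated above 0.1 mV, a true ratio from the
condition's Normal (cathodal 0.79/0.21, anodal 0.93/0.08, placebo
1.10/0.36), and per-trial amplitudes baseline × ratio × lognormal noise.
Trial noise is lognormal because MEP amplitudes are positive and
right-skewed, with σ_log = 0.15: deliberately modest, because the
condition-level SDs are *session-level* dispersions that already absorb
most trial-to-trial variability — doubling it up would inflate the cohort
SDs above their nominal values. Two small biases follow from the pipeline
itself and are worth knowing: trimming skewed trials biases block means
down by ~0.5%, and dividing by a noisy baseline biases ratios up by ~0.2%.
Both are second-order relative to the Monte-Carlo error of any cohort the
package simulates. A power check (the cathodal-vs-placebo test rejecting
at α = 0.05 in a majority of n = 12 cohorts) is a generator sanity check,
not an empirical claim about any real study.

What the generator does **not** emulate: session-order and time-of-day
effects, baseline drift within a session, responder/non-responder
subpopulations, or any TMS physics (resting motor threshold staircases and
baseline-adjustment rules exist only as the fixed trial counts and the
baseline truncation). Passing tests therefore show the *analysis chain* is
correct under the stated statistical structure, not that the structure
exhausts real MEP data.

## Validation: what the phantom studies show

- **Convergence** (4-shell sphere, scalp electrode pair at 30°/150°):
  relative L2 error of FDM scalp potentials against the analytic
  Legendre-series solution, on scalp voxels >20 mm from either electrode,
  falls monotonically ≈0.27 → 0.21 → 0.08 over 8 → 4 → 2 mm. The
  electrode-pair source is the TES-relevant solve; the 20 mm exclusion
  removes the point-electrode singularity, a modeling artifact.
- **Limitation — transcranial staircase bias**: for a *deep dipole*
  source, scalp potentials at 2 mm still over-estimate the analytic
  solution by ~15–17% in amplitude (pattern correlation >0.997). The
  analytic side was independently verified (a 1D radial finite-difference
  oracle per harmonic degree agrees to 1e-4; the dipole and injection
  series branches satisfy reciprocity to 2e-5), so this is the first-order
  staircase error of voxelized FDM across a 100:1 skull contrast — the
  reason production head-model solvers run at ≤1 mm. Montage *selection*
  is insensitive to it (ratios and rankings, not absolute amplitudes).
- **Reciprocity**: lead-field entries from electrode solves match explicit
  two-monopole dipole solves at the same grid anchor to solver tolerance
  (~1e-6 relative), as the symmetry of the stencil matrix dictates;
  comparing at exact (off-grid) centroids instead adds a few percent of
  interpolation difference.
- **Optimality**: on the 4-shell phantom the reciprocity montage
  out-doses essentially all (typically 100/100) random montages matched
  for electrode counts, per-channel cap and total current. This
  operationalizes "maximizes directional current density" without
  claiming global optimality over continuous current vectors, which the
  ranked-weighting heuristic does not provide (and constrained-optimization
  variants are deliberately out of scope).

Problem sizes used by the test-suite and the acceptance script — 8 mm
planning stacks (~6k unknowns), 4 mm validation spheres (~51k), a single
2 mm convergence point (~408k), cohorts of 12–1000 — were chosen as the
smallest sizes at which each claim is in its asymptotic regime; all run on
one CPU in well under an hour.

## Numerical and degenerate-input choices

- Zero-sum is enforced at 1e-9 relative on injection patterns and
  montages; the singular Neumann solve refuses anything else.
- Ranking ties break to the lowest electrode index; equal-magnitude
  selected voltages give every channel the full cap.
- Zero-variance paired differences return p ∈ {0, 0.5, 1} by sign, with a
  degenerate flag rather than NaN.
- Constant MEP blocks trim two (equal) trials and return the constant.
- Degenerate mesh triangles are removed with a warning count before
  parceling; opposing-normal patches are flagged as described above.
- An exclusion flag on the late-interval re-analysis reproduces
  single-participant sensitivity checks without hard-coding any exclusion.

## File formats

Volumes read/write as NIfTI (`RNifti`); meshes as ASCII PLY; electrode
sets as CSV or `.sfp`-style text; montages and parcellations as JSON/CSV;
cohorts as long-format CSV. The lead-field store is plain text (matrix CSV
plus a JSON sidecar with electrode ids, patch ids and the reference tag).
All coordinates are millimeters in a right-handed frame with the origin at
the volume corner.
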