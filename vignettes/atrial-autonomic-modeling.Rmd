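---
title: "Modeling autonomic modulation of left-atrial electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling autonomic modulation of left-atrial electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atriagp)
```

## Scope and model

`atriagp` simulates how parasympathetic (ganglionated-plexus, GP) and
sympathetic stimulation shape pulmonary-vein (PV) triggers and atrial
fibrillation (AF) wave dynamics in the human left atrium (LA). The stack has
four layers:

1. **Cell model.** The Courtemanche–Ramirez–Nattel (CRN) human atrial ionic
   model (21 state variables), with the Kneller acetylcholine-activated
   potassium current `IKACh` added to the total K⁺ current. All currents are
   expressed in pA/pF with a 100-pF membrane capacitance; concentrations in
   mM, time in ms, voltage in mV.
2. **Variants.** Regional and pharmacological modifications are carried by a
   `model_variant`: multiplicative conductance scalings, a depolarizing
   shift of the Na⁺ steady-state inactivation curves (h∞, j∞ evaluated at
   `V − shift`; the time constants are left unshifted), the local ACh
   concentration, and SR release/leak knobs (default 1).
3. **Tissue.** Monodomain reaction–diffusion on a 2D finite-difference sheet
   or an arbitrary triangulated surface, integrated by operator splitting.
4. **Analysis.** Per-beat AP features and EAD detection, virtual bipolar
   electrograms with CFAE cycle-length (CFAE-CL) mapping, time-delay-embedded
   phase with topological-charge phase-singularity (PS) detection and greedy
   tracking, and an AF/AT/termination classifier for virtual-ablation
   outcomes.

## Autonomic condition

Sympathetic stimulation is modeled as a homogeneous fold increase of the
L-type Ca²⁺ conductance (default ×7, within the 5–8-fold range reported for
isoproterenol), supported by a ×2 multiplier on the Na⁺/Ca²⁺ exchanger
current (`INaCa`) and a +10 mV depolarizing shift of the Na⁺ inactivation
curve, which widens the voltage window of Na⁺ influx. The NCX fold is
implemented as a plain multiplier on the `INaCa` term (the alternative —
scaling the maximal exchanger rate — is algebraically identical here because
the rate enters the current linearly). Parasympathetic stimulation is the
Kneller dose–response `IKACh` with ACh in μM; 0.05 μM is the default
stimulation level, and the lower 0.03 μM level used in some wave-dynamics
comparisons is a plain argument, not a separate mode.

```{r}
v <- apply_ans_stimulation(apply_pv_variant(model_variant()))
v
```

### The PV scaling table

The electrophysiological differences between PV-sleeve and LA cardiomyocytes
are applied as a named, user-overridable table of conductance factors
(`pv_factors()`): `gK1 ×0.5`, `gto ×0.6`, `gCaL ×0.75`, `gKr ×1.6 → 1.5`,
`gKs ×1.6`. These are transcriptions of the patch-clamp literature on PV
sleeves (reduced inward rectifier, transient outward and L-type currents;
augmented delayed rectifiers); exact factors vary between reports, so the
table is a configuration default, chosen once, and every test that involves
PV cells relies only on the relative property APD90(PV) < APD90(LA) — never
on the exact factors. Override with
`options(atriagp.pv_factors = list(...))`.

### AF electrical remodeling

`apply_af_remodeling()` multiplies `gK1 ×1.5`, `gto ×0.2`, `gCaL ×0.6`,
`gKur ×0.5`, composing with any existing scalings; it is the substrate used
to sustain fibrillation in the 3D runs.

## Numerics

* **Scheme.** Operator splitting per time step: Rush–Larsen updates for all
  gates (voltage-dependent gates from lookup tables over
  V ∈ [−150, 100] mV at 0.05-mV resolution, linearly interpolated; the
  Ca-dependent gates from their instantaneous steady states), forward Euler
  for V and the five concentrations, then one explicit diffusion step. The
  reaction time step defaults to **0.02 ms**; halving it to 0.01 or 0.005 ms
  changes the reported end-pacing baseline potential by < 0.01 mV, which is
  the package's convergence criterion for this protocol.
* **Dual implementation.** The full right-hand side exists twice: a readable
  R reference (`crn_derivatives()`) and the compiled kernel. The two are
  independently coded and the test suite requires agreement to 1 part in
  10⁹ on random valid states; the lookup-table stepping is additionally
  checked against trajectory-level features.
* **Diffusion.** Isotropic only (the target studies use a homogeneous,
  fiber-free LA). The default coefficient `D = 0.1 mm²/ms` was calibrated
  once so a planar wave on the 250-μm sheet conducts at ≈ 0.47 m/s
  (physiological atrial range 0.4–0.5 m/s); `measure_planar_cv()` is the
  shipped calibration utility. Grid domains use the 5-point Laplacian with
  no-flux boundaries; meshes use cotangent weights with barycentric area
  lumping (negative cotangents clamped for robustness; a uniform graph
  Laplacian is available as `method = "graph"` for poor meshes).
* **Stimulus.** Rectangular pulses, 2 ms wide, at twice the diastolic
  threshold found by the bisection utility `find_stim_threshold()`: −25
  pA/pF for an isolated control cell and −72 pA/pF for edge pacing of the
  autonomic 20×20 sheet (the edge column must also charge its neighbours).
* **Lesions.** Ablated nodes are clamped at rest, skipped by the reaction
  step and removed from the diffusion stencil rows and columns, so lesion
  rims are no-flux boundaries.
* **Degenerate inputs.** Zero-area triangles abort operator construction
  with the offending indices; non-finite voltages abort a run naming the
  node and time; gate boundedness is structural (Rush–Larsen relaxation
  toward an in-range steady state cannot overshoot).

## The 2D rate-change protocol

`run_2d_ead_protocol()` reproduces the pacing design used to probe late
phase 3 early afterdepolarizations (EADs): a 20×20 sheet of PV-variant cells
under the combined autonomic condition, paced at one edge 200× at a 100-ms
cycle length, after which the cycle length switches to 1000 ms. Reported
quantities: the diastolic potential immediately before the 200th stimulus at
a central probe, and per-beat EAD flags. The **first post-change beat** is
defined as the first beat delivered at the new cycle length: the onset edge
of the phenomenon in the *second* cycle length only makes mechanistic sense
if the EAD rides on the beat that follows the long pause (L-type recovery
plus residual Ca²⁺ load), so an EAD found during the pause itself is also
attributed to the change.

The EAD detector is an operational rule (thresholds exposed): after the
beat's peak, a local minimum between −60 and −20 mV followed by a rise of at
least 10 mV above the running minimum, with no stimulus in between.

### What this implementation finds

With the defaults above, rapid pacing elevates the pre-stimulus baseline of
the sheet to ≈ −70 mV (isolated cell: −71.8 mV), and the first post-change
beat shows the expected large Ca²⁺ transient with a strong inward NCX tail —
but the tail consistently falls ~0.2 pA/pF short of the outward
IKACh + IK1 + pump sum at the candidate take-off voltages, so **no late
phase 3 EAD fires** anywhere in the scanned neighbourhood (NCX ×1–4,
ICaL ×7–14, shifts to +27 mV, first cycle length 50–120 ms, second
780–880 ms), at any tested time step, and independently of the PV-table
choice within its literature range. The balance is self-stabilizing: raising
the Ca²⁺ load also speeds NCX-mediated Ca²⁺ removal, so the Ca²⁺
concentration available at the take-off voltage stays pinned near 1 μM.
The phenomenon is evidently a knife-edge property of the exact current
balance — consistent with the narrow parameter windows reported for it —
and this faithful CRN+Kneller implementation lands just on the stable side.
The protocol, detector and scans are all fully implemented and exercised so
the corresponding checks report the miss honestly rather than being skipped.

## The synthetic left atrium and the octopus GP model

Patient CT meshes are not available, so `generate_idealized_la()` builds a
parametric stand-in: an ellipsoidal shell (semi-axes 25×20×18 mm,
matching a ~45-mm LA diameter) from a subdivided icosahedron, with four
12°-radius PV ostium openings (left/right × superior/inferior, posterior
aspect) and a 38° mitral opening. Subdivision level 4 gives ≈ 4 700
triangles. Region labels mark each PV sleeve (7-mm geodesic extent from the
rim) and an anterior-septal Bachmann-bundle insertion patch. The construction
is checked structurally: exactly five boundary loops and Euler
characteristic χ = V − E + F = −3 (a sphere minus five open disks).

`generate_gp_octopus()` places one GP patch (4-mm radius) at the antrum of
each PV (LSGP, LIGP, RAGP, RIGP — exact clinical coordinates are not
published, so antral placement is parametric and overridable) and radiates
eight nerve branches per GP outward as geodesic polylines at near-uniform
tangent-plane angles (length 0.4× LA diameter by default; both are stated
defaults, not reproductions of measured anatomy). ACh is uniform on
GP ∪ nerve vertices and zero elsewhere — the spatial "higher near the GP"
concentration pattern emerges from branch-density geometry rather than from
an explicit gradient field. What the synthetic shell does *not* emulate:
wall-thickness variation, fiber anisotropy, fibrosis, the right atrium, and
true patient anatomy — so population-level wave-dynamics statistics from
patient cohorts are out of reach here, and 3D results should be read as
qualitative/directional only.

## 3D protocols

`run_3d_trigger_protocol()` paces the left superior PV at 100 ms (0–7 s)
concurrently with 1000-ms Bachmann-site pacing (simulated sinus rhythm), the
autonomic condition applied homogeneously and ACh acting through the GP
layout. Spontaneous PV activity is scored by stimulus attribution: a
PV-vertex activation with no stimulus anywhere in the preceding 300 ms is
spontaneous. On the synthetic shell this reproduces the trigger phenotype:
after rapid pacing stops, PV vertices fire sustained spontaneous
oscillations (cycle length roughly 300–600 ms, slow-upstroke,
sinus-node-like), which are present under the ICaL ×7 condition and absent
when no sympathetic modification is applied. The "control" here is the full
baseline (no ICaL fold, no NCX fold, no Na⁺ shift): applying the NCX and
Na⁺-shift components without the ICaL increase leaves cells parked in a
depolarized, inexcitable state after rapid pacing, which we consider
non-physiological rather than a meaningful control.

`induce_af()` burst-paces the Bachmann site of the AF-remodeled atrium
(stages of 25 pulses at ~130/110/95 ms, jittered ±5 ms by the seed — an
induction schedule chosen as a documented default) and then observes freely,
sampling voltage maps at 1 ms for phase analysis. Failure to induce is an
explicit result (`induced = FALSE`), not an error: on the smooth idealized
shell, sustained AF is much harder to obtain than on dilated, remodeled
patient anatomies, and the package does not promise it. Virtual ablation
(`ablation_pattern()`, `apply_ablation()`) supports GP-only lesions and
circumferential PV isolation with or without the GPs; band closure is
verified by graph connectivity (no path from any PV rim to the mitral rim),
and the band widens automatically (up to +3 mm) on meshes too coarse for the
nominal 2.5-mm annulus. The AF/AT/termination classifier uses operational
definitions (no clinical standard exists for simulations): termination = no
activations in the final 2 s; organized tachycardia = median per-node
cycle-length coefficient of variation < 10% in every subsequent 2-s window
with at most one concurrent long-lived (> 500 ms) phase singularity;
fibrillation otherwise.

## Analysis conventions

* **Phase** defaults to delay embedding (τ = 10 ms) against a 1-s sliding
  mean; the Hilbert-transform analytic signal is available behind
  `method = "hilbert"`. Constant-amplitude nodes are flagged invalid, not
  assigned a phase.
* **PS detection** is by topological charge on elementary plaquettes (grid)
  or consistently oriented triangles (mesh; triangles touching boundary
  vertices are excluded by default). The chirality sum over any closed
  region equals the boundary winding number — asserted per frame in the
  tests. Tracking is greedy nearest-neighbour with a 2-mm hop and 2-frame
  gap by default.
* **Electrograms** are bipolar-like: normalized distance-weighted sums of
  −dV/dt within 2 mm of each pole, poles 1.5 mm apart; normalization makes
  common-mode rejection exact. A deflection is a local maximum of |signal|
  above threshold (default 20% of the trace maximum) with a 40-ms
  refractory; CFAE-CL is the mean inter-deflection interval, undefined
  (flagged) below two deflections. The CFAE area uses CFAE-CL **≤ 120 ms**:
  the source material uses "≤ 120 ms" in the text and "< 120 ms" in a
  footnote; the package standardizes on ≤ and records the discrepancy here.
* **Directional GP effects.** The expected directional effects of switching
  GP ACh on during AF (shorter CFAE-CL, the decrease concentrated at GP
  areas, more numerous and shorter-lived PSs) are properties of sustained AF
  on patient geometries; with AF on the idealized shell not reliably
  sustained, the package asserts the building blocks (APD shortening under
  ACh, CFAE/PS estimator correctness, GP/CFAE overlap arithmetic) rather
  than the population-level orderings.

## Problem sizes used by the shipped checks

The automated checks run the full 200-beat 2D protocol (20×20 nodes,
≈ 22–24 s simulated) once plus two-point brackets at the reported parameter
edges, the property suite at cable/sheet sizes of 10–80 nodes per side, and
two 3D trigger runs on the ≈ 4 700-triangle shell over 9.5 s simulated.
These sizes were chosen so the whole suite completes on a single CPU in
well under half an hour while still exercising every protocol at the scale
the 2D study actually used.
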