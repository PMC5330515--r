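# atriagp

Simulation and analysis of autonomic (ganglionated-plexus) modulation of
left-atrial electrophysiology in R.

Ectopic beats from the pulmonary veins (PVs) trigger atrial fibrillation
(AF), and the epicardial ganglionated plexi (GPs) — clusters of autonomic
neurons whose nerves radiate across the atrium like an octopus — are
suspected co-conspirators: parasympathetic acetylcholine (ACh) shortens the
atrial action potential through the inward-rectifier current
I<sub>KACh</sub>, while sympathetic stimulation boosts the L-type Ca²⁺
current. Their combination favors late phase 3 early afterdepolarizations
(EADs), PV automaticity, and destabilized fibrillatory waves. `atriagp`
provides a tested, reusable implementation of this modeling chain for
researchers in computational cardiac electrophysiology:

* the **Courtemanche–Ramirez–Nattel (CRN)** human atrial ionic model
  (21 state variables, pA/pF convention) with the **Kneller** dose-dependent
  I<sub>KACh</sub>, solved by a monodomain reaction–diffusion scheme
  (operator splitting, Rush–Larsen gates, explicit diffusion) on 2D sheets
  and arbitrary triangulated surfaces (cotangent Laplacian), with a compiled
  kernel verified to 1 part in 10⁹ against an independent R reference;
* **model variants**: PV vs LA current scalings, chronic-AF electrical
  remodeling (I<sub>K1</sub> ×1.5, I<sub>to</sub> ×0.2, I<sub>CaL</sub>
  ×0.6, I<sub>Kur</sub> ×0.5), and autonomic stimulation (ACh 0.05 µM,
  I<sub>CaL</sub> ×7, NCX ×2, +10 mV Na⁺-inactivation shift);
* a **synthetic idealized left atrium** (ellipsoidal shell, four PV ostia,
  mitral opening, Bachmann-bundle site) with a parametric **octopus GP/nerve
  layout** carrying the spatial ACh field;
* **protocols**: the 2D rate-change (EAD) protocol, dual-site 3D PV-trigger
  pacing, burst AF induction, and virtual ablation (GP-only, circumferential
  PV isolation with/without GPs) with AF/AT/termination classification;
* **analysis**: per-beat AP features and EAD detection, virtual bipolar
  electrograms and CFAE cycle-length maps, phase via time-delay embedding,
  phase-singularity detection by topological charge, and trajectory
  tracking — each validated against analytic ground-truth fixtures.

## Worked example

Paced action potentials and the autonomic effect on APD:

```r
library(atriagp)

ctrl <- model_variant()                      # LA control cell
vag  <- model_variant(ACh = 0.05)            # parasympathetic stimulation

r <- simulate_cell(ctrl, stim_times = c(0, 1000, 2000, 3000), duration = 4000,
                   stim_amp = -25)
f <- extract_ap_features(probe_trace(r), stim_times = c(0, 1000, 2000, 3000))
tail(f$apd90, 1)
#> [1] 293

r2 <- simulate_cell(vag, stim_times = c(0, 1000, 2000, 3000), duration = 4000,
                    stim_amp = -25)
f2 <- extract_ap_features(probe_trace(r2), stim_times = c(0, 1000, 2000, 3000))
tail(f2$apd90, 1)
#> [1] 47
```

The control cell's APD90 of 293 ms is the canonical CRN value at 1 Hz;
0.05 µM ACh collapses it to 47 ms — the substrate for PV arrhythmogenicity.

Tissue-level conduction and rotor analysis:

```r
# planar conduction velocity on the 250-µm sheet at the default diffusivity
measure_planar_cv(tissue_grid(80, 3, 250, D = default_diffusion()))
#> [1] 0.4672897            # m/s, physiological atrial range

# phase-singularity detection on an analytic spiral fixture
fx <- make_fixture("analytic_spiral", center = c(15.2, 15.3))
detect_phase_singularities(fx$data$phase[, , 1])
#>      x    y chirality cell
#> 1 14.5 14.5         1  421
```

The full 2D autonomic protocol (200 beats at a 100-ms cycle length, then the
cycle length jumps to 1000 ms):

```r
res <- run_2d_ead_protocol()
res$diastolic_end_pacing    # baseline potential before the 200th stimulus
#> [1] -73.47191            # mV; rapid pacing elevates it from -81 toward -71
res$ead_first_beat          # late phase 3 EAD on the first slow beat?
#> [1] FALSE
```

Rapid pacing under combined autonomic stimulation elevates the diastolic
potential by ~8 mV (the isolated cell settles at −71.8 mV; conduction
alternans in the coupled sheet deepens the sheet value slightly). In this
implementation the late phase 3 EAD itself does **not** fire: the inward
NCX tail on the first slow beat stays ~0.2 pA/pF short of the outward
K⁺/pump sum at every candidate take-off voltage — see the methods vignette
(`vignettes/atrial-autonomic-modeling.Rmd`) for the full current-budget
analysis and what that implies.

On the synthetic atrium, the 3D trigger protocol reproduces PV
arrhythmogenicity directly:

```r
geom <- generate_idealized_la()             # ~4,700-triangle LA shell
lay  <- generate_gp_octopus(geom, seed = 1) # 4 GPs + radiating nerves, ACh 0.05
trig <- run_3d_trigger_protocol(geom, lay, duration = 10500)
trig$spontaneous$count
#> [1] 671                  # spontaneous PV activations after pacing stops

ctrl3d <- run_3d_trigger_protocol(geom, lay, ical_fold = 1, ncx_fold = 1,
                                  ina_shift = 0, duration = 10500)
ctrl3d$spontaneous$count
#> [1] 0                    # no sympathetic stimulation, no triggers
```

## Layout

```
R/                  cell model, variants, tissue solver, geometry/GP layout,
                    protocols, wave analysis, fixtures, stats, orchestration
src/                compiled CRN/monodomain kernel (Rcpp)
tests/testthat/     unit, property and end-to-end reproduction tests
scripts/acceptance.R   headline-quantity recomputation (above)
inst/cli/atriagp.R  thin command-line front end (simulate | fixtures | stats)
vignettes/          methods vignette: model, assumptions, numerics, limits
```
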