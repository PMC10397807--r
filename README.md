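# denfit

Density-guided flexible fitting of atomic models into cryo-EM maps, with
automated frame selection and pixel-size calibration — an R toolkit for the
desk-scale end of model refinement.

## The problem

Fitting an atomic model into a cryo-EM density map means balancing two
objectives: agreement with the experimental density and sound
stereochemistry. Pushing a model into a map with ever-growing forces will
always improve the density fit, eventually at the cost of deformed
geometry; stopping too early leaves real conformational change unmodelled.
A second, subtler failure mode lives upstream: if the detector pixel size
is mis-calibrated, the whole map is uniformly scaled, and any model refined
against it is stretched or compressed to match.

`denfit` implements an automated protocol for both problems:

1. **Forward model.** Atoms become isotropic 3D Gaussians of width
   `σ = 2 × pixel_size × 0.425` (0.68–0.731 Å for maps at 0.80–0.86
   Å/pixel), normalised to unit integral and truncated at 4.5 σ.
2. **Density-guided dynamics.** Overdamped Langevin dynamics on
   `E = E_restraint − k·S`, where `S` is the normalized cross-correlation
   between the model-generated density and the target map, and
   `E_restraint` is a structure-based potential (observed bonds, angles,
   soft steric repulsion). The bias constant `k` follows *adaptive force
   scaling*: every feedback interval `Δt` it grows by `exp(Δt/τ)` while
   the similarity stalls and shrinks by the same factor while it improves
   (`τ = 4` ps, `k_start = 10` kJ/mol, 300 K by default).
3. **Selection.** Every 2 ps a frame is recorded with its similarity, FSC
   average (mean Fourier shell correlation up to a 2.88 Å threshold) and a
   stereochemical quality score (weighted bond-RMS + angle-RMS +
   clashes/1000; lower is better; an external GOAP executable can be
   plugged in). The chosen model is the best-quality frame within the
   FSC-average plateau, then annealed by heavy-atom-restrained
   steepest-descent minimization.
4. **Pixel-size calibration.** The target map is relabelled over a grid of
   candidate voxel sizes (no resampling), seed models from an unbiased
   simulation are fitted into each, and the pixel size with the best mean
   quality score is the calibration estimate. A per-axis
   radius-of-gyration diagnostic (ratios to a reference model about the
   membrane normal and two perpendicular axes) flags scale errors
   independently.

Everything runs on synthetic fixtures (a toy β-barrel of pseudo-atoms,
forward-modelled targets and half-maps with controlled noise and
deliberately mislabeled pixel sizes), so the full pipeline is testable
offline; real MRC/CCP4 maps and PDB models are read and written with the
same functions.

## Worked example

```r
library(denfit)

spec   <- fixture_spec(n_strands = 6, strand_length = 6, radius = 6, box = 32)
sys    <- make_toy_barrel(spec)                    # ground-truth model + topology
maps   <- make_target_maps(sys$model, spec)        # noisy target + half-maps
target <- normalize_map(maps$full)

start <- perturb_model(sys$model, 2, seed = 7)     # 2 A-perturbed starting model
ali   <- rigid_body_align(start, target, global = FALSE)
traj  <- run_fit(ali$model, sys$topology, target,
                 fit_config(seed = 7, timestep = 0.02, max_time = 20))
print(traj)
#> <fit_trajectory> 11 frames over 20 ps, terminated by max_time
#>   similarity 0.3166 -> 0.3302, fsc_avg 0.4991 -> 0.4971, final k 73.89 kJ/mol

sel <- select_best_frame(traj)
print(sel)
#> <selection_result> frame 2 (t = 2 ps): quality 1.909, plateau of 1 frames
#>   (eps = 0.01, max fsc_avg 0.6054)

final <- energy_minimize(sel$model, sys$topology)
print(stereo_score(final, sys$topology))
#> <quality_score> total 1.564 (bond RMS 0.076 A, angle RMS 0.160 rad, clashes/1000 0.00)
```

The selected and minimized model improves on both axes that matter: RMSD to
the ground truth drops from 2.00 Å to 1.63 Å, and map correlation rises
from 0.317 (rigid-body fit) to 0.417 — the fitted-beats-rigid-body
behaviour the selection rule is designed to deliver. (Absolute correlations
are capped well below 1 by the fixture's deliberate voxel noise.)

Calibration runs the same machinery over a pixel-size grid:

```r
seeds <- generate_seed_models(sys$model, sys$topology, n_seeds = 5,
                              config = fit_config(seed = 42, timestep = 0.02))
cal <- run_pixel_scan(seeds, sys$topology, mislabeled_map,
                      pixel_grid = seq(0.80, 0.88, by = 0.01),
                      config = scan_config)
cal$selected_pixel   # minimum of the mean-score curve; plot(cal) draws it
```

On a target forward-modelled at 0.84 Å/pixel but labelled 0.86, the mean
quality score traces a parabola with its minimum at 0.84 — the scan
recovers the true pixel size from the model geometry alone.

A command-line front end wraps the same functions
(`inst/scripts/denfit.R`): subcommands `fit`, `calibrate`, `metrics`,
`fixture` and `score`, with YAML configuration and a JSON run manifest per
invocation.

## Scope

The restraint engine is structure-based and solvent-free (fits from
different solvation environments are known to converge to superimposable
models); explicit-solvent MD, micrograph re-processing, and external
scorers (GOAP, MolProbity, FSC-Q) are out of scope — the windowed
local-quality score included here is a clearly-labelled simplified analog,
not the published FSC-Q algorithm.
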