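---
title: "Density-guided model fitting and pixel-size calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-guided model fitting and pixel-size calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denfit)
```

## The problem

A cryo-EM reconstruction is a 3D density map; an atomic model built into it
should simultaneously explain the density and keep sound stereochemistry.
`denfit` automates that balance at desk scale: it forward-models atoms into
density, drives the model into the map with an adaptively scaled similarity
bias on top of a structure-based restraint potential, monitors the fit with
Fourier shell correlation (FSC) averages, picks the best stereochemical
frame within the FSC-average plateau, and anneals it with restrained
minimization. Because a mis-calibrated detector pixel size uniformly scales
the map — and therefore stretches or compresses every model refined against
it — the same machinery doubles as a pixel-size calibrator: fits are scored
over a grid of relabelled voxel sizes and the size with the best mean
stereochemical score wins.

## The forward model and the bias

Each atom becomes an isotropic 3D Gaussian of width sigma, weighted by its
amplitude (atomic number by default) and normalised to unit integral. The
width is tied to the target map's sampling,

    sigma = 2 * pixel_size * 0.425,

so a map at 0.80–0.86 Å/pixel is spread with sigma between 0.68 and
0.731 Å. Kernels are truncated at 4.5 sigma (a documented choice; the
neglected 3D tail mass is below 2e-4, so per-atom integrals stay accurate
to better than 1e-3) and evaluated on per-atom stencils for O(n) cost. The bias energy is `E = -k * S`, with `S` the Pearson
cross-correlation between the model-generated density and the normalized
target map; forces are the analytic gradient of `S` through the Gaussian
spread. Map normalization uses all voxels by default — whether the original
protocol masked the similarity statistics is not stated anywhere we could
check, so unmasked is the default and a mask argument is provided.

## Dynamics and adaptive force scaling

The fitting dynamics is overdamped Langevin (Euler–Maruyama) on
`E_restraint - k * S` rather than full Newtonian MD in explicit solvent:
refined models from solution, detergent and lipid environments are known to
be effectively superimposable, which licenses a solvent-free restraint
engine. The restraint topology is read off the starting structure — bonds
are heavy-atom pairs within a cutoff (1.9 Å for all-atom models, ~1.15 bead
spacings for coarse fixtures) restrained at their observed lengths, angles
at their observed values, with a soft-core repulsion between non-excluded
heavy pairs. Its minimum is the starting geometry, so the stereochemical
score below measures exactly the deformation the density imposes.

The bias force constant `k` follows adaptive force scaling: every feedback
interval `dt_fb`, if the similarity failed to increase, `k` grows by
`exp(dt_fb / tau)`, otherwise it shrinks by the same factor; `tau` defaults
to 4 ps. The published start value is typeset ambiguously ("10e 1 kJ/mol");
we read it as 10 kJ/mol and expose `k_start`. Stalled fits therefore
escalate exponentially — `k = k_start * e^n` after `n` stalled intervals —
until the fit improves, the force cap terminates the run (the
excess-adapted-force stop), or the time limit (default 3 ns) is reached.
The update period `dt_fb` is not published; we reuse the 2 ps evaluation
cadence by default.

Key defaults, all configurable through `fit_config()`:

| parameter | default | meaning |
|---|---|---|
| `k_start` | 10 kJ/mol | initial bias force constant |
| `tau` | 4 ps | feedback time constant |
| `feedback_interval` | 2 ps | adaptive update period |
| `eval_stride` | 2 ps | frame/metric recording period |
| `temperature` | 300 K | Langevin bath (0 = gradient flow) |
| `timestep` | 0.002 ps | integration step |
| `max_time` | 3000 ps | time limit |
| `k_cap` | 1e6 kJ/mol | excess-force termination |
| `resolution_threshold` | 2.88 Å | FSC-average threshold |
| `gamma` | 50 amu/ps | friction (mobility 1/gamma) |

The friction is a numerical choice: with the 300 K default it yields
per-step thermal displacements of a few hundredths of an Å at the timesteps
used here, enough exploration to diversify seeds without destabilising the
bonded network. Each run draws all randomness from one seeded generator, so
trajectories are bitwise reproducible from `config$seed`.

## Metrics, selection, minimization

Every `eval_stride` the engine records the similarity, the FSC average
(mean FSC over shells up to the resolution threshold, 2.88 Å by default —
"mean of shells up to the threshold" is the simplest faithful reading of an
FSC average with a threshold, the original implementation being
unpublished), and a stereochemical quality score. The score is a weighted
sum of bond-RMS (Å), angle-RMS (rad) and clashes per 1000 atoms (steric
gap 0.4 Å, the usual clashscore convention), with weights (10, 5, 0.1)
chosen so typical well-refined fixtures land around 0.5–1.5; it stands in
for knowledge-based potentials such as GOAP (lower = better), and an
external GOAP executable can be plugged in where available
(`external_goap()`).

The selected frame is the best-quality frame within the FSC-average
plateau. The plateau is defined deterministically as the superlevel set
`fsc_avg >= (1 - epsilon) * max(fsc_avg)` with `epsilon = 0.01` — published
descriptions of the plateau are visual, so a formula had to be imposed; the
superlevel-set form admits both contiguous late-trajectory plateaus and
isolated near-maximal frames, and `epsilon` is exposed. Ties break to the
earliest frame. The selected model is then annealed by steepest-descent
minimization with backtracking, by default with harmonic positional
restraints on heavy atoms (`k_pos` 1000 kJ/mol/Å²), to a maximum-force
tolerance of 1e-4. The published tolerance appears once as kJ/mol and once
as kJ/mol/nm; we treat it as a force (energy/length) tolerance.

A windowed local-quality score (`local_quality()`) compares model-to-map
agreement with half-map reproducibility in cubic windows (default 15
voxels): `q = FSC_avg(model, full) - FSC_avg(half1, half2)` per window,
mapped to atoms at their nearest voxel, with the conventional ±0.5
interpretation bands. This is a deliberately simplified analog of published
half-map local-quality measures with its own sign semantics — it is not the
Scipion FSC-Q algorithm and is not expected to reproduce deposited FSC-Q
values.

## Pixel-size calibration

`relabel_pixel_size()` changes the voxel-size header without resampling:
the calibration question is "what physical scale should this same
reconstruction have?", so interpolation would only blur the comparison. The
scan (`run_pixel_scan()`) takes seed models from an unbiased (no-density)
simulation — seven by default, matching the reference ensemble — and, for
each candidate pixel size, relabels the target, recomputes sigma from that
pixel (keeping the forward model internally consistent), rigid-body aligns,
fits, selects, and records the selected frame's quality. Failed runs
degrade to n−1 averaging with a warning rather than aborting the scan. The
estimate is the pixel size with the lowest mean score; means come with
standard errors (sd/sqrt(n)) and a `plot()` method. The default grid is
0.80–0.86 in 0.01 steps (Methods-style; the wider 0.80–0.88 grid used in
the tests stresses both flanks).

The companion diagnostic is the per-axis radius of gyration
(`rg_diagnostic()`): Rg about the membrane normal and two perpendicular
axes, normalized to a reference model. Its founding property is geometric —
a model uniformly scaled by `s` has every per-axis ratio exactly `s` — so
ratios drifting from 1 during fitting flag a mislabeled pixel size, with
per-axis resolution for anisotropic systems.

## Synthetic fixtures and what they do (not) show

The built-in generator emulates the study system at bead resolution: a
β-barrel-like arrangement of `n_strands x strand_length` pseudo-atoms (one
carbon-like bead per residue, exact 3.8 Å spacing, 20° strand tilt) on an
8 Å cylinder, boxed at the nominal 0.86 Å/pixel of the original
reconstruction (48 voxels default; the test suite uses a 6x6 barrel in a
32-voxel box to keep runs fast). Target maps are forward models plus
Gaussian voxel noise of sd 0.05 — about 5% of the peak bead density, enough
to keep global correlations in a realistic 0.3–0.7 band rather than
trivially near 1. Half-maps get independent noise of sd*sqrt(2), so their
average reproduces the full map's noise level in expectation, the
convention that makes half-map FSC measure reproducible signal. All
fixtures are bit-reproducible from (spec, seed) and writable to standard
PDB/MRC.

What these fixtures do not emulate: real transfer functions, B-factor
falloff, detergent/lipid density, radiation damage, or all-atom
side-chain chemistry. Passing tests therefore demonstrate the machinery —
alignment, bias gradients, adaptive scaling, selection, calibration
bookkeeping — not the attainable accuracy on experimental reconstructions.

## Numerical and experimental-design choices

* Problem sizes in the test suite are deliberately small: 36-bead barrels
  in 32-voxel boxes, 4–20 ps trajectories at 0.01–0.02 ps timesteps, 20
  seeded repetitions of the end-to-end experiment, 2 repetitions of the
  9-pixel x 5-seed calibration scan. These sizes were chosen once, as the
  smallest systems that exercise every code path with clear margins.
* The end-to-end fitting experiment perturbs the barrel by 2 Å, fits into a
  self-generated noisy target at 300 K with default adaptive scaling, and
  compares the selected+minimized model against a local
  ("fit-in-map"-style) rigid-body baseline. The baseline is local rather
  than global because the barrel is quasi-symmetric: a global orientation
  search may land in a symmetry-equivalent pose of equal correlation,
  which is correct map-wise but meaningless for RMSD-to-truth bookkeeping.
* The calibration scan and the Rg-scaling experiment run at temperature 0
  with a strong fixed bias (tau effectively infinite). At 300 K with the
  default weak bias, thermal bond fluctuations (~0.11 Å RMS at k_bond =
  200 kJ/mol/Å²) drown the ~0.05–0.11 Å strain signal that label errors of
  0.01–0.02 Å/pixel imprint; the zero-temperature, strong-coupling limit
  measures the same mechanism — geometric strain versus label error —
  deterministically. This mirrors the long-time limit of adaptive force
  scaling, whose escalation eventually dominates thermal noise in full-length
  runs.
* Rotation parametrisation is axis-angle (Rodrigues); the coarse alignment
  search probes 7 axes x 11 angles plus identity before Nelder-Mead
  refinement, and the aligned model never correlates worse than the input.
* Degenerate inputs fail loudly: constant maps (normalization, similarity),
  non-cubic grids (FSC), thresholds beyond Nyquist, models outside the
  grid, zero-mass models, truncated MRC files.
* FSC shells with numerically zero power in either map (the DC shell of
  mean-zero maps) are reported as `NA` and excluded from averages.

## Known limitations

* The restraint potential is structure-based; it cannot discover chemistry
  the starting model lacks, and conformational transitions across barriers
  (multi-minimum selection) are out of scope.
* `local_quality()` is a simplified windowed score, not deposited FSC-Q.
* MRC I/O covers the little-endian single-volume files produced by modern
  cryo-EM software (modes 0/1/2/6); extended headers are skipped.
* The pixel-size scan relabels headers; re-processing raw micrographs at
  the corrected size is upstream reconstruction work.
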