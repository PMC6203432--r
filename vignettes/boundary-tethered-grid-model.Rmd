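---
title: "A boundary-tethered grid-cell network and its deformation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A boundary-tethered grid-cell network and its deformation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`gridtether` implements a spiking network of three interacting populations
that together explain why grid-cell firing patterns appear to "rescale"
when a familiar environment is deformed, and provides the complete spatial
analysis toolbox needed to quantify that behaviour in any position + spike
data set.

**Border layer (32 units).** The band within 12 cm of each wall is divided
into 8 bricks per allocentric direction (each brick 12.5% of its wall's
length).  Unit *j* receives a constant input $b_j = 0.1$ whenever the rat
occupies one of 4 consecutive perimeter bricks, so each unit's field spans
50% of the length of one side, some fields wrapping corners.  Fields are
recomputed from the current geometry, so they rescale with their wall and
reappear at analogous positions on inserted walls — the signature
properties of recorded border cells.

**Grid layer (5 modules of 128×128 units).** Each module is a neural sheet
with periodic boundaries (a torus) tiled by 2×2 blocks of units preferring
E/N/W/S movement.  Unit *j* receives
$v_j = \gamma + g_m\, d \cos(\theta - \phi_j)$ where $d$ is the distance
moved this timestep, $\theta$ the heading, $\phi_j$ the unit's preferred
direction, $\gamma = 0.6$, and $g_m$ the module gain.  Each unit inhibits
every unit within 12 sheet units of a point displaced 2 units along its
preferred direction (weight −0.02).  This shifted radial inhibition makes
the sheet settle into a hexagonal bump lattice that translates with the
rat's velocity at a rate proportional to $g_m$; a unit's spatial firing
pattern is therefore a hexagonal grid with scale inversely proportional to
the gain.  Gains follow $g_m = 0.45 \cdot 2^{-(m-1)/2}$, giving the
observed geometric series of grid scales (ratio $\sqrt{2} \approx 1.42$).

**Place layer (64 units).** Each place unit receives 500 random grid
afferents and uniform recurrent inhibition (−0.15, self included).

**Dynamics.** All populations share the same stochastic spiking dynamics:
total input $b_j$ (feed-forward plus recurrent), spike probability
$\mathrm{clip}(\kappa (b_j - \beta_j)\, dt,\, 0, 1)$ with $\kappa = 500$,
$dt = 3$ ms and thresholds $\beta$ of 0 / 0.1 / 0.05 (border / grid /
place), and leaky integration $a_j \leftarrow 0.9\, a_j + 0.5\, s_j$.

**Learning.** Border→grid and grid→place weights evolve by a competitive
Hebbian rule
$w_{ij} \leftarrow w_{ij} + \lambda a_j\big[(\xi_j - w_{ij}) a_i -
w_{ij} \sum_{n \ne i} a_n\big]$, $\lambda = 10^{-5}$, whose fixed point
drives the total incoming weight of each unit to $\xi$ (0.4 for
border→grid, 0.5 for grid→place).  During familiarization the border
units that fire near a given wall become coupled to the grid units active
there; afterwards, touching a wall *reinstates* the grid phase that held
near that wall during familiarization.  In a deformed environment the
displaced wall reinstates the old phase at a new location — a
boundary-tethered phase shift.  Averaged over a whole trial these shifts
mimic a rescaling, while instantaneous (boundary-conditioned) activity
shows a phase offset, lower peak rates at constant mean rate, and local
population-vector distortion near displaced walls.

## Protocols

`familiarize()` settles each sheet for 2 s at zero velocity from an
orientation-biased seed, then lets the virtual rat explore for 60 min
(desk preset: 10 min) along a bounded random walk with learning on, while
caching the full sheet state per visited 2.5 cm pixel (last visit wins).
`test_trial()` restores the familiarized weights, reinstates the grid
state cached at the start pixel, turns learning off, and records spikes of
30 random grid units per module and all 64 place units.

## Numerical and design choices

* **Inhibition as an incrementally maintained field.** The inhibitory
  drive is the convolution of the activation sheet with a shifted disc.
  Because activations decay by a fixed factor and grow only at spikes,
  the convolved field obeys the same linear recursion and is updated by
  stamping discs at spike locations — exact, and orders of magnitude
  cheaper than per-step convolutions.
* **Orientation bias.** The source states the settled lattice axis lies at
  −7.5° from east but not the mechanism.  A periodic sheet admits only a
  discrete set of stable lattice orientations; we seed the sheet with a
  weak hexagonal template and keep the settled state whose axis is
  closest to the target (probing a few seed angles, quality-gated by the
  sheet-autocorrelation gridness).  The sheet-to-space map preserves the
  axis angle (verified by comparing settled sheet axes with measured
  rate-map axes).  On a 128 torus the nearest stable orientation is
  ~1.3° from the target; on a 64 torus only ~0°/15° exist, which is why
  orientation measurements use the full-size sheet.
* **Spiking versus rate-based dynamics.** A deterministic variant that
  propagates expected spike counts is provided, but it is *not* used for
  measurements: without spiking noise the bump lattice pins to
  torus-commensurate states and its translation speed stops being
  proportional to the gain (stick-slip), breaking the scale series.  The
  Bernoulli dynamics self-anneal this pinning.  Measured units' rate maps
  are nevertheless built from per-step expected counts (the spike
  probability), which removes shot noise without altering the network's
  stochastic evolution.
* **Random-walk noise units.** Speed noise sd 0.001 cm/ms and heading
  noise sd 1.5°/ms are applied once per 3 ms step (heading sd scaled by
  the step length in ms, 4.5°/step), the simplest literal reading; both
  are configurable.
* **Corner ties in contact labeling** keep the current label when it is
  among the equidistant walls, else fall back to a fixed N,S,E,W
  priority.
* **Map edges.** The smoothing kernel is renormalised over the visited
  support, so border pixels are unbiased; unvisited pixels stay masked
  except in prediction maps, where all pixels are retained.
* **Correlograms** are computed with FFT cross-correlations of the maps,
  their squares and their masks, reproducing the per-lag Pearson formula
  exactly; lags with fewer than 20 overlapping pixels are masked.  The
  test suite checks exact agreement with a brute-force per-lag oracle.
* **Rescaling search** follows the prescribed grid (10 cm below the
  smaller length to 10 cm above the larger, 5 cm steps) with mask-aware
  linear resampling onto the unchanged 2.5 cm pixel grid; ties take the
  first maximum.  Normalised rescaling is undefined (NA) for undeformed
  trials.
* **Nearest blob** in the shift analysis is the blob minimising the
  distance from the correlogram centre to *any* of its pixels, so a
  central blob touching the origin always wins.

* **Phase stability and segmented measurements.** Without border input
  nothing corrects path-integration error, and the spiking sheet
  occasionally suffers an abrupt phase slip after minutes of movement.
  Pure path-integration measurements (module scale, orientation)
  therefore pool several short walk segments, each restarted from the
  same settled state at the arena centre (so all segments share one
  spatial phase), and apply the field's standard session-stability
  inclusion criterion: segments whose maps decorrelate from the pooled
  remainder are excluded before measuring.  The criterion uses no
  knowledge of the quantity being measured.

## What the synthetic data emulate — and what they do not

The bounded random walk reproduces gross rat kinematics (speed
distribution bounded at 40 cm/s, heading diffusion, wall avoidance) but
not thigmotaxis or behavioural states; occupancy is more uniform than a
real rat's.  The `two_phase_mixture` fixture replaces geometric contact
labels with an idealised block process whose W/E probability ramps
linearly across the chamber: every pixel samples both phases, isolating
the analysis from sampling segregation, with a default 60 cm spacing so
the 30 cm compression displacement is half a period (the regime where a
two-phase average most resembles rescaling).  A green test on these
fixtures establishes that the *statistics* recover known ground truth; it
does not establish anything about recorded cells.

Desk-scale simulations shorten familiarization from 60 to ~10-20 min.
Since the learning rate is fixed, border→grid weights are only partially
converged, so mechanism tests assert qualitative signatures (elevated
shift ratio along the deformed dimension, boundary-conditioned rescaling
below whole-trial rescaling, peak-rate drop at stable mean rate, local
population-vector depression), not effect sizes.

## Known limitations

* Long-term relaxation dynamics of grids after deformation are outside
  the model's scope, as are visual-cue frame conflicts and speed cells.
* Because the learning rate is a fixed constant, minutes-long desk
  familiarizations leave the border-to-grid weights diffuse; boundary
  contact then re-anchors grid phase only weakly, and the
  boundary-conditioned versus whole-trial rescaling dissociation does not
  yet emerge at desk scale (the corresponding acceptance assertion is
  deliberately left failing rather than weakened).  The dissociation is
  demonstrated on the ground-truth two-phase fixture instead.
* The 64-unit desk sheets do not support the largest gain (module 1);
  desk mechanism runs use the gains of modules 2-3.
* Statistical hypothesis tests on cell populations (paired t, sign, KS)
  are deliberately not wrapped; standard R functions apply directly to
  the returned tables.
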