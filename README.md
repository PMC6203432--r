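# gridtether

Grid cells fire on a hexagonal lattice of locations; border cells fire
along particular walls.  When a familiar chamber is compressed or
stretched, time-averaged grid maps appear to rescale — yet the underlying
cause need not be a true rescaling.  `gridtether` implements a spiking
network in which experience-dependent border-to-grid coupling makes grid
phase *re-anchor to the most recently contacted boundary*, together with
the analysis toolbox needed to detect that mechanism in any position +
spike data set: occupancy-normalised rate maps, masked auto-/cross-
correlograms, grid scale and gridness, boundary-conditioned rate maps
with occupancy-matched subsampling, grid-shift and rescaling statistics,
boundary-tethered rate-map prediction, and population-vector correlation.

The network: 32 border units (fields 12 cm deep, spanning 50% of one
wall), five velocity-driven continuous-attractor grid modules (128×128
toroidal sheets; shifted radial inhibition, radius 12, weight −0.02,
centre shift 2; gains `g_m = 0.45·2^{-(m-1)/2}`, so consecutive grid
scales have ratio √2 ≈ 1.42), and 64 place units with 500 random grid
afferents.  All units share stochastic spiking
`P(spike) = clip(κ(b−β)dt, 0, 1)` (κ = 500, dt = 3 ms) with leaky
integration `a ← 0.9a + 0.5s`, and the two feed-forward pathways learn by
a competitive Hebbian rule whose incoming totals converge to ξ (0.4
border→grid, 0.5 grid→place).

## Worked example

Simulate two adjacent grid modules along a 4-minute random walk in a
150 × 150 cm arena and measure their grid scales:

```r
library(gridtether)
set.seed(1)
env  <- make_environment("rectangle", 150, 150)
traj <- random_walk(env, duration_s = 240)
sim  <- simulate_grid_modules(gains = module_gain(1:2), nside = 128,
                              traj = traj, env = env, n_record = 6,
                              seed = 2)
for (m in 1:2) {
  scales <- sapply(1:6, function(u) {
    map <- rate_map(traj, NULL, env, spike_counts = sim[[m]]$counts[u, ])
    grid_scale(correlogram(map, map))$scale_cm
  })
  cat(sprintf("module %d: mean grid scale %.1f cm\n", m, mean(scales)))
}
```

```
module 1: mean grid scale 26.2 cm
module 2: mean grid scale 36.8 cm
```

The scale ratio 36.8 / 26.2 ≈ 1.40 reproduces the geometric module series
(√2 ≈ 1.42): halving the velocity gain doubles nothing — it scales the
grid by √2 per module step because gains descend by `2^(-1/2)`.

The full protocol — familiarize a naive network, then test it in a
compressed chamber and run the deformation statistics — is:

```r
cfg <- network_config("desk")          # 2 modules, 10-min familiarization
net <- init_network(cfg, seed = 1)
net <- familiarize(net, make_environment("rectangle", 150, 150), seed = 2)
tt  <- test_trial(net, make_environment("rectangle", 100, 150), seed = 3)
lab <- label_boundary_contacts(tt$traj, tt$env)
# per-unit shift of opposing boundary rate maps, occupancy-matched:
spk <- subset(tt$spikes$grid, unit == tt$rec_grid[1])$t
grid_shift(tt$traj, spk, lab, tt$env, scale_cm = 36, dimension = "x")
```

## Layout

* `R/`, `src/sim.cpp` — arena & trajectories, border layer, attractor
  engine (Rcpp), place layer, rate-map metrics, deformation statistics,
  fixtures, JSON config + CLI (`inst/cli/gridtether.R`).
* `tests/testthat/` — unit, property and acceptance tests (brute-force
  oracles live in `helper-oracles.R`).
* `vignettes/boundary-tethered-grid-model.Rmd` — the model, its
  assumptions, numerical choices and limitations.
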