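# smtkinetics

Kinetic analysis of live-cell single-molecule tracking (SMT) data for
chromatin-binding proteins — built around the question of how ATP-dependent
chromatin remodelers (RSC, SWI/SNF, INO80, ISW2, CHD1, ISW1) find and
occupy their promoter targets in budding yeast. The package is aimed at
people analyzing trajectory tables from fast-tracking (10 ms/frame) and
slow-tracking (250 ms/frame) movies, and at anyone who wants the downstream
target-search arithmetic without microscope data at all.

It implements, as composable tibble-in/tibble-out functions:

* **Fast tracking** — per-trajectory MSD and diffusion coefficients with
  the R² ≥ 0.8 filter; two-component Gaussian mixtures of log₁₀D; the
  two-state (bound/free) jump-length-distribution fit with axial
  defocalization correction (`F_bound`, `D_bound`, `D_free`, σ); a
  two-state displacement HMM (Baum–Welch + Viterbi) with bound-only /
  free-only / transitioning trajectory sub-classification; the circular
  radius-of-confinement fit.
* **Slow tracking** — gap-tolerant track linking (≤ 2 missing frames,
  < 3 px), dwell-time survival curves, double-exponential fits
  `P(t) = f_sb e^(−k_sb t) + f_tb e^(−k_tb t)`, photobleaching correction
  against an H2B reference (`τ_sb = 1/(k_sb − k_sb,H2B)`), and bootstrap
  errors.
* **Occupancy calculus** — from `(F_bound, f_sb, τ_sb, τ_tb, N_targets,
  N_molecules)` to the site-specificity ratio r_s, number of non-specific
  trials, free time, search time τ_search, sampling interval
  `SI = (τ_search + τ_sb)·N_targets/N_molecules`, and temporal occupancy
  `τ_sb/SI`, with Monte-Carlo error propagation.
* **Occupancy simulation** — event-driven occupied/vacant traces of a
  promoter target and co-occupancy statistics for several factors.
* **Synthetic data** — a two-state Brownian trajectory generator (Markov
  state switching, localization noise, nuclear boundary, photobleaching,
  frame-sampled axial defocalization) and dwell-time generators, with
  ground truth, so the whole pipeline is testable without real movies.

Fitted objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*`
visualizations; `run_fast_pipeline()` / `run_slow_pipeline()` chain the
stages under one master seed.

## Worked example

Temporal occupancy of RSC at its promoter targets, from published kinetic
parameters (bundled in `remodeler_kinetics()`; τ_tb is an assumed
representative value, flagged as such in the table):

```r
library(smtkinetics)

rsc <- dplyr::filter(remodeler_kinetics(), factor == "RSC")
derive_search_kinetics(F_bound = rsc$F_bound, f_sb = rsc$f_sb,
                       tau_sb = rsc$tau_sb, tau_tb = rsc$tau_tb,
                       N_targets = rsc$N_targets,
                       N_molecules = rsc$N_molecules)
#> # A tibble: 1 × 8
#>     rs1   rs2    rs n_trials tau_free tau_search sampling_interval occupancy
#>   <dbl> <dbl> <dbl>    <dbl>    <dbl>      <dbl>             <dbl>     <dbl>
#> 1  27.0  2.70  14.9     15.9    0.395       14.6              16.7     0.300
```

Reading: with a stable-binding fraction of 27% and residence times of
5.0 s (stable) vs 0.5 s (transient), a searching RSC molecule makes ~16
non-specific binding trials (r_s ≈ 15 non-specific sites per specific
site), each free excursion lasting ~0.4 s, giving a search time of ~15 s.
With 3702 genomic targets and ~4355 molecules per nucleus, a given target
is visited every ~17 s (the sampling interval) and is occupied ~30% of the
time — matching the published 30 ± 7.3% for RSC despite its short 5 s
residence time.

The same number falls out of the stochastic trace simulator:

```r
tr <- simulate_trace(tau_sb = 5.0, SI = 17, duration = 1e6,
                     factor = "RSC", seed = 1)
occupied_fraction(tr)
#> [1] 0.2951458
autoplot(simulate_trace(5.0, 17, duration = 500, factor = "RSC", seed = 1))
```

And a measurement-side example on synthetic fast-tracking data:

```r
sim <- simulate_two_state_trajectories(sim_config(
  D_bound = 0.05, D_free = 1.0, k_off_state = 0.9, k_on_state = 1.1,
  sigma_loc = 0.025, nucleus_radius = 5, n_trajectories = 5000, seed = 11))
fit <- fit_two_state(build_jump_length_data(sim$trajectories), seed = 3)
fit
#> <twostate_fit> F_bound = 0.542, D_bound = 0.0511, D_free = 0.924 um^2/s,
#>   sigma = 0.024 um (SSE 0.001932, 68404 jumps, 6 lags)
```

against a ground-truth stationary bound fraction of 0.55.

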