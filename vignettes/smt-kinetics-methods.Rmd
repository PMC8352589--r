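---
title: "Models and methods behind smtkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtkinetics)
```

`smtkinetics` implements the quantitative core of a live-cell
single-molecule tracking (SMT) study of chromatin-binding proteins —
ATP-dependent chromatin remodelers in budding yeast being the motivating
system. Two imaging regimes feed the analysis. *Fast tracking* (10 ms
frames, high laser power) resolves both chromatin-bound and freely
diffusing molecules and yields the fraction bound. *Slow tracking* (250 ms
frames, low power) motion-blurs free molecules so that only chromatin-bound
ones register; the temporal length of a track is then an apparent chromatin
dwell time. A target-search calculus combines both regimes with genomic
target counts and nuclear copy numbers into the temporal occupancy of a
target site, and an event-driven simulator renders occupancy as stochastic
on/off traces.

This vignette records the models, the tunable parameters, the numerical
choices, and the known limitations. All empirical statements below are
properties exercised by the package's test suite on synthetic data; the
package itself computes every number shown in the README.

## The synthetic-data generator

Real microscope data for this class of experiment are large, binary, and
instrument-specific, so the package is validated end to end against its own
forward model, `simulate_two_state_trajectories()`. It emulates exactly the
data structure the estimators assume:

* two diffusive states (bound/free) with isotropic 2D Brownian steps of
  per-coordinate variance $2 D_\text{state}\,\Delta t$;
* Markov switching evaluated once per frame with probabilities
  $1 - e^{-k\,\Delta t}$ (sub-frame switching is ignored; the bias is
  negligible while $k\,\Delta t \ll 1$, which holds for all defaults);
* a reflecting circular nuclear boundary (radial reflection);
* independent Gaussian localization noise of s.d. `sigma_loc` per
  coordinate and frame;
* geometric track lengths (photobleaching) with mean `n_frames_mean`;
* axial defocalization: a 1D Brownian z-coordinate started uniformly in a
  slab of depth `dZ`; a molecule in the free state found outside the slab
  at a frame time is lost from that frame on.

Defaults are chosen as a realistic yeast configuration: frame interval
10 ms, $D_\text{bound} = 0.03$ and $D_\text{free} = 1.0\ \mu m^2/s$,
`sigma_loc` 0.025 µm, `dZ` 0.6 µm, nucleus radius 1.0 µm, and a mean
pre-bleach track length of 20 frames. The track-length default is a
declared package choice (effective photobleaching-limited track lengths are
instrument-dependent and are not published for this experiment class);
nothing downstream depends on it beyond statistical power.

Slow-tracking data are generated dwell-first by `simulate_dwell_events()`
rather than as blurred trajectories, mirroring how that regime is analyzed:
event durations are drawn from a stable/transient exponential mixture,
truncated by an exponential photobleaching time, and quantized *up* to
whole 250 ms frames (a molecule present during any part of a frame is
detected). `simulate_reference_standard()` produces the single-exponential
apparent dwell times of a chromatin-incorporated reference (histone H2B)
whose loss is photobleaching-dominated.

What the generator deliberately omits: dye photophysics (blinking, dark
states), camera noise, motion blur within fast-tracking frames, anomalous
diffusion, and spatial heterogeneity of binding sites. Passing tests
therefore demonstrate correctness of the estimators *under the stated data
model*, not robustness to every instrumental artifact of real movies.

## Fast tracking I: MSD, log10 D mixtures, confinement

`compute_msd()` gives the time-averaged MSD per trajectory;
`fit_diffusion_coefficient()` regresses MSD on lag time over lags 2–5 and
converts the slope to $D = \text{slope}/(2d)$ with $d = 2$. Lag 1 is
excluded because localization error inflates it most strongly; no explicit
intercept correction for $\sigma$ is applied, so fitted $D$ values are
apparent. Fits with $R^2 < 0.8$ are flagged rejected, the conventional
filter for per-trajectory D histograms.

`fit_log10D_mixture()` decomposes the population of $\log_{10} D$ values
into slow (bound) and fast (free) Gaussian components using model-based
clustering (EM with deterministic hierarchical initialization, via
*mclust*), so repeated runs agree without a seed. A fit is flagged
degenerate when one component holds ≥ 95% of the weight or the means are
closer than twice the larger component s.d.

`fit_confinement()` fits the first 10 MSD points of bound-classified
trajectories to the circular confinement model
$\mathrm{MSD}(t) = R_c^2\,(1 - e^{-4 D t / R_c^2})$, rejecting fits with
RSS above $10^{-5}\ \mu m^4$, $R_c$ above 0.3 µm, or a preliminary linear
$R^2$ below 0.1 (confined MSDs are strongly curved, hence the lenient
threshold). The RSS threshold is interpreted in µm⁴ on the first-10-point
residuals; the unit convention is stated here because published parameter
lists for this filter typically leave it implicit.

## Fast tracking II: the two-state jump-length fit

The central fast-tracking estimator (`fit_two_state()`) fits the pooled
jump-length cumulative distributions at lags $n\Delta t$, $n = 1..6$, with
a two-state kinetic model. Each state contributes a Rayleigh CDF with
scale$^2 = 2(D\,n\Delta t + \sigma^2)$ ($\sigma$ enters twice per
displacement coordinate — once per localization — giving the
$+\sigma^2$ inside the scale). Jump collection follows the standard
configuration for this experiment class: 0.01 µm bins, six time points,
at most four jumps per trajectory per lag, jumps above 2 µm discarded.
Free parameters and boxes: $F_\text{bound} \in [0,1]$,
$D_\text{bound} \in [0.0005, 0.1]$, $D_\text{free} \in [0.15, 25]$
µm²/s, $\sigma \in [0.01, 0.1]$ µm. Optimization is `L-BFGS-B` on
$(F_\text{bound}, \log_{10} D_\text{bound}, \log_{10} D_\text{free},
\sigma)$ with three starts; all lags are weighted equally.

**Defocalization.** Fast free molecules leave the axial detection window
(depth `dZ` = 0.6 µm) and are undercounted at long lags; uncorrected, this
inflates the apparent bound fraction. Two corrections are implemented:

* `defocalization_fraction()` — the classical survival of a molecule in a
  *continuously absorbing* slab, from the eigenfunction series
  $P(t) = \sum_{k\ \text{odd}} \tfrac{8}{k^2\pi^2}
  e^{-k^2 \pi^2 D t / dZ^2}$, truncated at terms $< 10^{-10}$ (with a
  short-time closed form when the series would need excessive terms).
* `sampled_slab_survival()` — the survival under *per-frame monitoring*: a
  camera only loses a molecule that is outside the slab at a frame time.
  This is computed exactly (to quadrature accuracy) by propagating the
  in-slab density with the Gaussian step kernel restricted to the slab
  (trapezoid rule, 151 nodes).

The distinction matters: with $D = 1\ \mu m^2/s$ and 10 ms frames the
per-frame z-step s.d. (0.14 µm) is a quarter of the slab, and the
continuously absorbing model overstates the per-frame loss substantially.
`fit_two_state()` therefore defaults to the frame-sampled survival, and
additionally averages it over the possible jump start frames (a jump at
lag $n$ starting at frame $j$ is observed only if the molecule stayed
detectable for $j + n$ frames since track start). On 5000-trajectory
synthetic sets this weighting recovers $F_\text{bound}$ within ±0.02 and
both diffusion coefficients within ±8% across
$F_\text{bound} \in \{0.35, 0.55, 0.80\}$; the continuous correction is
retained as an option (`z_correction = "continuous"`) and biases
$F_\text{bound}$ low by ≈ 0.05 on the same data. State switching within a
lag is not modeled, matching the standard two-state treatment.

**Known limitation — confinement.** The jump model assumes unconfined free
diffusion. In a realistic 1 µm-radius yeast nucleus the free component's
long jumps are compressed, and the fitted $D_\text{free}$ comes out ~15%
low while $F_\text{bound}$ stays within ±0.03. The recovery validations
therefore run at a 5 µm boundary where the model's assumptions hold;
estimates from small-nucleus data should be read as effective values —
as is equally true of the published tools this estimator parallels.

## Fast tracking III: displacement HMM

`fit_hmm_two_state()` is a two-state maximum-likelihood HMM over
displacement sequences: emissions are squared consecutive-frame
displacements, exponential with mean $4 D_\text{state} \Delta t$;
Baum–Welch runs over all trajectories jointly (scaled forward–backward,
vectorized across tracks), with restarts drawn from diffusion coefficients
log-uniform in $[0.001, 16]$ µm²/s and state dwell times of 2–20 frames.
Fixing the model at two states replaces variational-Bayes model selection
deliberately: the biological question is a bound/free dichotomy, and the
reference analyses in this field fix the state count to two as well.

Numerical notes: the likelihood trace is stored and is non-decreasing (EM
guarantee, asserted in tests); states are relabeled after fitting so
$D_1 < D_2$; a fit with $|\log_{10}(D_2/D_1)| < 0.1$ is flagged degenerate
and refuses to decode. Localization error is *not* modeled in emissions
(matching common practice), which inflates the apparent bound-state D by
$\sigma^2/\Delta t$ — at default noise (0.025 µm, 10 ms) that is
0.0625 µm²/s, larger than $D_\text{bound}$ itself. Decoding therefore
still separates the states (the free state is another order of magnitude
faster), but classification-accuracy validations use near-zero noise so
that they measure segmentation quality, not the documented emission-model
bias.

`classify_displacements()` uses Viterbi decoding — contiguous runs, which
the sub-classification rule needs — rather than per-step posterior
thresholding. `subclassify_trajectories()` applies the three-way rule:
*bound only*, *free only*, or *transitioning* (both states present with at
least two consecutive displacements in each). Trajectories with both states
but no two-displacement run in each (e.g. B,F,B,F) do not meet any
definition; they are reported as `mixed_unclassified` and excluded from the
three-class percentages rather than silently folded into a class.

## Slow tracking: residence times with photobleaching correction

`survival_curve()` builds the empirical $1-\mathrm{CDF}$ of dwell times,
keeping events of at least three frames (shorter apparent events are
dominated by free molecules transiting the focal volume).
`link_with_gaps()` reconstructs slow-tracking tracks from localizations
first: greedy nearest-neighbour linking, bridging up to two missing frames
when the next localization lies strictly within three pixels (0.107 µm
pixels). Linking ambiguities are resolved by distance, then earliest
frame, then lowest index — a deterministic completion of a rule that
published trackers leave unspecified. Linking partitions the input; no
localization is dropped.

`fit_double_exponential()` fits
$P(u) = f_{sb} e^{-k_{sb} u} + (1 - f_{sb}) e^{-k_{tb} u}$, with
$f_{sb} + f_{tb} = 1$ and $u = t - (\text{min\_frames} - 1)\Delta t$
measured from the retention boundary of the minimum-length filter. The
shift is not cosmetic: a left-truncated two-exponential mixture is again a
unit-weight two-exponential mixture in $u$ with the *same rates*, so the
constrained fit estimates $k_{sb}$ and $k_{tb}$ without truncation bias,
and $f_{sb}$ is the stable fraction among events that pass the filter.
Least squares on the survival curve is the default (matching how such
curves are fit in practice); rate pairs with $k_{tb}/k_{sb} < 2$ are
flagged ill-separated. A robustness ladder of starts plus a Nelder–Mead
fallback handles effectively single-exponential inputs.

`correct_residence()` applies the reference correction
$\tau_{sb} = 1/(k_{sb} - k_{sb,\text{ref}})$ and
$\tau_{tb} = 1/(k_{tb} - k_{sb,\text{ref}})$, where the reference rate is
the apparent *stable* rate of H2B imaged under identical conditions
(photobleaching/defocus dominated). Subtracting the stable reference rate
from the transient rate as well follows the source formulas exactly, even
though one could argue for a transient-specific reference; fidelity was
chosen over opinion. When $k_{sb} \le k_{\text{ref}}$ the residence time
is beyond the photobleaching-limited measurable range and the function
raises an error rather than reporting a negative or infinite time — this
situation occurs in practice for very stable mutants.

`bootstrap_errors()` resamples events with replacement (default 100
replicates), refits, re-corrects, and reports the s.d. per parameter,
counting failed replicates explicitly. The unweighted curve fit gives every
unique time point equal say, so its bootstrap error does not shrink exactly
like $n^{-1/2}$ (the sparse tail grows with $n$); the `weighted` option
(at-risk weighting) restores regular scaling and is used for that property
test.

## The occupancy calculus

`derive_search_kinetics()` chains the closed-form calculus:

* $r_{s,1} = (\tau_{sb}/\tau_{tb})(1/f_{sb} - 1)$ (time interpretation),
  $r_{s,2} = 1/f_{sb} - 1$ (probability interpretation), averaged to
  $r_s$; $N_\text{trials} = 1 + r_s$;
* $\tau_\text{free} = \frac{\left[(1 + r_s)\tau_{tb} + \tau_{sb}\right]
  (1/F_\text{bound} - 1)}{2 + r_s}$, obtained by solving the bound-fraction
  balance
  $F_\text{bound} = \frac{N_\text{trials}\tau_{tb} + \tau_{sb}}
  {N_\text{trials}\tau_{tb} + \tau_{sb} + (N_\text{trials}+1)\tau_\text{free}}$
  for $\tau_\text{free}$ (the closed form is verified in tests by plugging
  the derived quantities back into the balance: the input $F_\text{bound}$
  is reproduced to machine precision for 1000 random parameter sets);
* $\tau_\text{search} = N_\text{trials}\tau_{tb} +
  (N_\text{trials} + 1)\tau_\text{free}$;
* $SI = (\tau_\text{search} + \tau_{sb}) N_\text{targets}/N_\text{molecules}$;
* occupancy $= \tau_{sb}/SI$, deliberately *not* capped at 1 — published
  estimates reach 94 ± 41%, and truncating would hide saturation; a
  warning is issued above 1.

Errors propagate by Monte Carlo (`propagate_errors()`): inputs drawn from
independent truncated Gaussians, pushed through the chain, with the s.d.
per output reported. Independence is an assumption of convenience — the
measured inputs come from different experiments, so cross-correlations are
unavailable in any case.

The bundled `remodeler_kinetics()` table carries the literature-derived
parameter bundles for RSC, SWI/SNF, INO80 and ISW2 (fractions bound,
stable fractions and residence times, search times where published,
sampling intervals, occupancies, genomic target counts, and the RSC copy
number derivable by inverting the SI formula). The transient residence
time is *not* a published constant for these factors; the table ships a
representative 0.5 s flagged `assumed`, and every function treats
$\tau_{tb}$ as a free input.

## Occupancy traces

`simulate_trace()` renders a target's occupancy as an alternating renewal
process: occupied durations exponential with mean $\tau_{sb}$, vacant
durations exponential with mean $SI - \tau_{sb}$, so a cycle averages one
sampling interval and the long-run occupied fraction is $\tau_{sb}/SI$.
The simulation is event-driven (no time discretization), and the initial
state is drawn from the stationary distribution — with exponential
durations this makes the trace exactly stationary, so even short (500 s)
display traces need no burn-in. `co_occupancy()` overlays independent
traces by exact interval arithmetic and reports each Boolean combination
of bound factors. Steric exclusion between co-bound factors is not
modeled.

## Problem sizes and reproducibility

Validation sizes were chosen to hold estimator error well below the
assertion tolerances while keeping the default test run in minutes:
5000 trajectories per two-state recovery point, 2000 dwell events with 100
bootstrap replicates, 800 trajectories for HMM accuracy, $10^6$ s
occupancy traces, $10^5$ Monte-Carlo walkers for the slab-survival oracle
(with Brownian-bridge crossing corrections per step, since naive Euler
monitoring is biased high by an amount larger than the comparison
tolerance). Every stochastic function takes a `seed` and restores the
caller's RNG state; the pipeline drivers fan a single master seed out to
per-stage seeds by stable hashing, so one integer reproduces a whole run.
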