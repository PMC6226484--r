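---
title: "Photon-by-photon likelihood analysis of binding kinetics and transient-complex lifetimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-by-photon likelihood analysis of binding kinetics and transient-complex lifetimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In an immobilized-molecule smFRET binding experiment a labeled molecule on a
surface binds and releases a partner from solution, and the detector stream
records individual photons — an arrival time and a channel (donor or
acceptor) for each. The apparent FRET efficiency of each kinetic state (the
acceptor fraction of its photons, uncorrected for leak or detection
efficiency) differs between the bound and unbound states, so the photon
stream carries the full binding/unbinding kinetics at the time resolution of
single photons. `tcphoton` analyses such streams without binning:

* maximum-likelihood estimation of two-state binding parameters
  (`fit_two_state`), optionally with acceptor blinking as two extra hidden
  states (`fit_four_state`);
* Viterbi segmentation of the stream into bound/unbound dwells and
  extraction of single-transition windows (`viterbi_path`,
  `find_transitions`, `extract_segments`);
* estimation of the lifetime of the transient complex (TC) — the short-lived
  intermediate through which binding proceeds — from a likelihood-difference
  scan (`delta_lnL_scan`) or a joint fit with the TC efficiency free
  (`fit_joint_six`);
* donor–acceptor cross-correlation analysis (`cross_correlation`,
  `fit_relaxation`);
* photon-trajectory simulators that make every stage testable with known
  ground truth (`simulate_ctmc_photons`, `recolor_trajectory`,
  `simulate_transition_segments`).

## The likelihood

For a trajectory of `N` photons with colors `c_i` and interphoton intervals
`tau_i`, the likelihood under a continuous-time Markov model with rate
matrix `K`, diagonal apparent-efficiency matrix `E` and equilibrium vector
`p_eq` is

    L = 1' [ prod_{i=2..N} F(c_i) exp(K tau_i) ] F(c_1) p_eq

with `F(acceptor) = E` and `F(donor) = I - E`. For a short segment known to
contain a single transition, `p_eq` and the summing row vector are replaced
by occupancy vectors `v_ini`, `v_fin` pinning the start and end states
(`endpoint_vectors`).

Numerics: `exp(K tau)` is applied through the eigendecomposition of `K`
(all models in the package — two-state binding, its Kronecker sum with a
two-state blinking chain, and the birth–death TC chains — have real
spectra; a complex code path guards near-defective cases). The propagated
vector is renormalized to unit sum after every photon with the log norms
accumulated, so 10^6-photon trajectories do not underflow. On trajectories
short enough to check, the implementation agrees with a brute-force
`Matrix::expm` product to 1e-8 relative (enforced in the test suite).

## Kinetic models

All models share the state ordering (B, TC, U), bright states before dark:

* **Two-state** (B, U): rates `k_A_app` (apparent association,
  pseudo-first-order) and `k_D`; bound fraction
  `p_B = k_A_app / (k_A_app + k_D)`.
* **Four-state** adds acceptor blinking: dark-state entry is proportional to
  illumination, `k_d = k_0 (n / n_0)` with `n` the trajectory's mean count
  rate and `n_0 = 100` photons/ms fixed; recovery `k_b` is
  intensity-independent; dark states emit at the donor-leak level `E_d`
  (default 0.06). The equilibrium is the outer product of the binding and
  blinking equilibria.
* **Three-state TC** (B, TC, U): the TC exits to both neighbours at the same
  rate `k_TC` (a deliberate symmetry — the data cannot resolve the two exit
  barriers), so the TC lifetime is `t_TC = 1/(2 k_TC)`. The binding rates
  are divided by `rate_reduction` (default 1000) so that a 0.4–3 ms segment
  effectively contains one transition; only likelihood *differences* are
  interpreted, so this rescaling cancels.
* **Six-state** is the three-state chain replicated in the acceptor bright
  and dark manifolds with identical kinetic rates in both.

## The lifetime scan and its zero

`delta_lnL_scan` computes `delta lnL(t) = ln L(t) - ln L(0)` over a grid of
candidate lifetimes (default 50 log-spaced points, 0.5 us – 10 ms), summing
single-transition segment likelihoods. `ln L(0)` is the instantaneous-
transition reference. A mathematical point that matters: as `t_TC -> 0` the
three-state chain does *not* converge to the two-state chain with the same
reduced rates — every TC visit branches 1/2 to each neighbour, so the limit
is the two-state chain with *halved* rates. The reference therefore uses
`k'/2`, which makes `delta lnL(0) = 0` hold identically (the package's
nesting tests verify the limit numerically). The rescaling is invisible in
practice because only differences along the scan are interpreted.

Decision rule (95% confidence at ±3 log-units, configurable): if the scan
peak exceeds +3, the lifetime is the location of the maximum, refined by
continuous maximization between the neighbouring grid points, with a
standard error from the local curvature; grid ties resolve to the smaller
(conservative) lifetime. Otherwise only an upper bound is reported: the
crossing of −3, located by linear interpolation on `log t`. Both the
larger-`t` and smaller-`t` crossings are stored; the headline bound is the
larger-`t` crossing, which is the only one a peakless decreasing curve has.

With the TC efficiency fixed, `E_TC = (E_B + E_U)/2` (the scan's
`fixed-midpoint` mode, matching how the blinking and efficiency parameters
are pre-estimated by `fit_blink_at_instantaneous` at the `t -> 0` limit).
Alternatively `fit_joint_six` maximizes over
`(E_B, E_U, k_b, p_b, E_TC, t_TC)` simultaneously; when the true `E_TC`
lies below the midpoint this fit finds it and generally returns a longer
lifetime, at the price of a larger `t_TC` standard error (nested-model
logic). With segments containing no dark excursions the blinking pair
`(k_b, p_b)` is unidentifiable (singular Hessian block), so
`fit_joint_six(blink = FALSE)` drops to the three-state model with four
free parameters.

## Optimization and errors

Rates are optimized in log space and efficiencies/probabilities in logit
space (BFGS, relative tolerance 1e-8); parameter excursions that invalidate
the model score a large finite penalty rather than aborting. With no
starting values supplied, 5 jittered multistarts are run; a user-supplied
`init` runs a single start. Standard errors are the square roots of the
diagonal of the inverse numerical Hessian (finite differences, step 1e-4 in
transformed coordinates), mapped back to the natural scale by the delta
method.

## The synthetic-data world

`simulate_ctmc_photons` draws the kinetic state path by Gillespie
simulation, emits photons as a homogeneous Poisson process at the configured
count rate, and colors each photon acceptor with probability equal to the
occupied state's efficiency. Defaults mirror the experimental regimes: the
ionic-strength kinetics series uses ~50–100 photons/ms and apparent rates of
order 10^2 s^-1 with bound/unbound efficiencies 0.6/0.25; TC-lifetime
material uses 300–900 photons/ms; the folded-pair (barnase/barstar-like)
system uses E_B = 0.75 against a donor-leak unbound level of 0.06 with
rates of order 1–10 s^-1. Emission is state-independent Poisson because the
interval-preserving recoloring protocol (below) treats interval statistics
as state-independent.

Acceptor photobleaching has two deliberate modes. With the acceptor on the
immobilized molecule (`"immobilized"`), a bleach switches emission to the
donor-leak efficiency permanently. With the acceptor arriving on the
binding partner (`"partner"`, the folded-pair labeling), a bleach only
blinds the current bound period — the molecule passes through a hidden
bound-bleached state that looks unbound and resumes normal signalling at
the next binding event. The partner mode is what makes apparent dissociation
faster and the apparent bound fraction smaller, and it is the regime in
which fixing `p_B` from trajectory start states (which bleaching cannot
distort) repairs the rate estimates; the residual few-percent error of the
fixed-`p_B` fit in our tests is the binomial sampling error of the
start-state fraction plus a small contamination of unbound dwells by the
hidden bound-bleached dwells. The simulated bleach rate in the tests is
`k_D / 3`, consistent with trajectories that show several binding events
before bleaching.

`recolor_trajectory` implements the interval-preserving simulator: photon
times are kept bitwise and only colors are redrawn, with an exponentially
distributed TC region (mean `t_TC`) split symmetrically about the
transition-interval midpoint (the symmetric split is the minimal reading of
"centred"; drawn and window-truncated durations are both recorded) and dark
intervals drawn from the blinking kinetics recolored at E = 0.06.
`simulate_transition_segments` builds ready-to-scan windows this way with
uniform-Poisson photon times and the transition at the window centre.

What a green test does *not* establish: the generator has no detector dead
time or afterpulsing, no diffusing background, no gamma-factor or distance
dynamics within states, and the recoloring places exactly one TC per
segment. Conclusions about real data quality (e.g. how many segments a real
condition yields) are outside its scope.

## Statistical behaviour worth knowing

* **Fixed-midpoint scan (t1-type recovery).** At 200 segments, 500
  photons/ms and a 183 us truth, the refined argmax is unbiased with ~8%
  replicate-to-replicate spread, of which ~7% is the sampling error of the
  200 exponential TC durations themselves — the estimator adds little on
  top of the irreducible noise.
* **Joint free-E_TC fit (t2-type recovery).** At the weak contrast
  `E_TC = E_U + 0.05` the joint ML estimate of `t_TC` runs ~10% low at 200
  segments: the fit reassigns the U-side edge of the TC to the unbound
  state (the fitted `E_U` creeps up by ~0.005). This is an intrinsic
  small-sample property of the estimator — a profile likelihood with all
  efficiencies pinned at truth still peaks slightly below the realized mean
  drawn duration — and is well inside the factor-1.5 band used for
  acceptance.
* **Null-case upper bound (t3-type).** For instantaneous transitions the
  −3 crossing scales with the data volume: 150 segments at 500 photons/ms
  put it at ~3.5 us, 900 photons/ms pull it near ~2 us, and doubling the
  segments tightens it further (the test suite checks the monotonicity on
  nested data). A sub-2 us bound at 150 x 500 photons/ms is not reachable
  in this stated world; see the package's decision notes.

## Numerical and degenerate-input choices

Tolerances: rate-matrix column sums must vanish within `1e-12 max|K|`,
stationarity within `1e-10 max|K|`; likelihood agreement with the oracle at
1e-8 relative; optimizer relative tolerance 1e-8. Zero-probability photon
sequences return `-Inf` (flagged) rather than erroring; segments with
`-Inf` reference likelihood are excluded from scans with a warning. Viterbi
ties break toward the lower state index (bound first). Transition times are
reported as interphoton-interval midpoints because the true switch time is
unidentifiable within an interval. Residence filtering (default 200 us,
configurable) merges sub-threshold excursions into the surrounding state
rather than deleting photons. The start-state classifier for `p_B` uses the
mean efficiency of a configurable initial window (default 50 ms) against
the midpoint threshold; choose the window well below the expected dwell
times.

## Known limitations

Dissociation cannot be distinguished from acceptor bleaching when the
unbound state is donor-only — hence the first-binding-event filter and the
fixed-`p_B` correction rather than a bleach-rate model. The TC is a single
state with equal exit rates; multi-state or asymmetric intermediates are
out of scope. All efficiencies are apparent; no gamma/background correction
is applied anywhere.
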