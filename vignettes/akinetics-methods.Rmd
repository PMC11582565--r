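---
title: "Modelling ligand-gated domain motions of adenylate kinase from nanopore recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ligand-gated domain motions of adenylate kinase from nanopore recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akinetics)
```

## The system and the model

Adenylate kinase (AK) interconverts ATP + AMP and 2 ADP. Its rigid core
carries two mobile domains: the LID (over the ATP site) and the NMP domain
(over the AMP site). Trapped in a nanopore, the enzyme's conformation
modulates the ionic current: four sub-levels of the blocked current (M, M1,
M2, M3) report the open, NMP-closed, LID-closed and doubly-closed
conformations, while ligand binding itself is electrically silent.

`akinetics` models this as a continuous-time Markov chain (CTMC) over ten
states. Each state combines a conformation with a ligation number (marked
by asterisks): `M0, M1, M1*, M, M*, M2*, M2**, M**, M1**, M3**`, in the
fixed row order used throughout the package. `M0` is an auxiliary state
absorbing sporadic shallow current excursions near -180 pA that are too
frequent to censor. The generator (Q-matrix) has non-negative off-diagonal
elementary rate constants, rows summing to zero, and two
concentration-scaled association steps: the first ligand binds at
`k1 * [ATP]` and the second at `k2 * [AMP]` (both per mM; the ADP model
reuses the same topology with both steps scaled by `[ADP]`).

Two *endosteric* couplings — allosteric effects carried by the reactants
themselves — are encoded structurally:

* the ATP-induced effect: the second ligand cannot bind while the LID is
  open (no `M* <-> M**` transition);
* the AMP-induced effect: the LID open/close rates of the binary
  (`r1`/`rm1`) and ternary (`r3`/`rm3`) complexes are distinct.

Variant `V3` keeps both effects. Variant `V1` removes the second (ties
`r3 := r1`, `rm3 := rm1`); variant `V2` removes the first (restores
`M* <-> M**`, reusing the same `k2`/`km2` rates as `M2* <-> M2**`). Each
variant therefore deletes exactly one endosteric effect while keeping the
other; the source description states only which effect each variant
eliminates, so this one-effect-at-a-time reading is our interpretation,
and likewise the ADP variant is built by analogy (single ligand species
driving both binding steps on the same topology). The rate list carries
`r2`/`rm2` for completeness of the `r1..r4` naming scheme, but the printed
rate matrix never uses them; they are housed, never placed in the
generator, and excluded from the free-parameter lists (22 free rates for
V3/V2/ADP, 20 for V1).

## Likelihood

The chain is discretized at the recording interval,
`Gamma = exp(dt * Q)` with `dt = 0.2` ms by default, equal to the sampling
interval so that no transition faster than the sampling is lost to
coarser discretization. Rates are stored in s^-1 and the conversion to
ms^-1 happens only inside `discretize()`.

Emissions are grouped Gaussians: states with the same LID/NMP arrangement
share one mean and standard deviation exactly. Default level means derive
from the measured residual-current fractions against an open-pore current
of -433.3 pA: M = -199.3, M1 = -211.0, M2 = -221.0, M3 = -233.1 pA, with
M0 = -180 pA and a common sd of 8 pA (within the measured 7-10 pA range).

The likelihood of a trace `y_1..y_T` is
`L = delta' (prod_t B_t) 1` with `B_t = Gamma diag(phi(y_t))` and `delta'`
the stationary distribution of `Gamma`. Note the ordering: the stationary
prior is propagated through `Gamma` once *before the first emission*,
which differs from the common textbook convention
(`delta' diag(phi(y_1)) Gamma ...`) by one transition; we follow the
model's stated form. The forward vector is renormalized to unit sum at
every step and the log normalizers accumulated, so the log-likelihood is
exact and underflow-free; `stationary_distribution()` is computed from
`Gamma` at each trace's own concentrations (which concentrations
parameterize the prior is not stated in the source; per-trace is the
natural reading for independent recordings). Independent traces multiply:
`joint_loglik()` sums per-trace log-likelihoods, rebuilding `Gamma` per
concentration condition from the shared rates.

## Estimation

`fit_model()` maximizes the joint log-likelihood over the variant's free
rate constants plus (optionally) the emission level means, the shared
emission sd, and per-trace baseline offsets:

* rates are optimized in log10 space; the default bounds 1e-1..1e6 s^-1
  map to the box [-1, 6]. Log-parameterization is our choice for
  conditioning (the original estimation worked in native space with
  case-specific bound adjustments, which are exposed here as
  `bound_overrides` in `fit_config()`);
* level means may float within +/- 3 pA of their defaults (the source
  says they were optimized "within a short interval" per segment without
  giving the width; 3 pA is well below half the smallest level
  separation, ~10 pA, so levels cannot swap), and the shared sd within
  [7, 10] pA;
* bounded quasi-Newton iterations (`L-BFGS-B`) with forward-difference
  gradients, at most 200 iterations, multi-started from six random
  log-uniform initial points derived deterministically from the seed
  (a start whose line search aborts is restarted once from its stopping
  point with a fresh Hessian approximation). The
  original used an interior-point method with step tolerance 1e-3; that
  tolerance has no exact L-BFGS-B analogue, so `step_tol` is mapped onto
  the optimizer's relative function-decrease criterion
  (`factr = step_tol * 1e12`), with the iteration cap doing the same work
  of bounding effort per start.

`compare_variants()` fits each variant independently on the same traces
and compares raw maximal log-likelihoods (the variants are structural
hypotheses, not a nested penalty family; AIC is reported as a separate
convenience column only). After the random multistarts, each variant is
re-polished from the other variants' optima: the shared rate naming makes
every optimum a valid start everywhere, and since V1's optimum is exactly
expressible in V3 (tied rates), the richer model can never be reported
below its own special case merely for lack of a good starting point — a
failure mode we observed with purely random starts on these multimodal
likelihood surfaces. `bootstrap_confidence()` is deliberately
labelled plumbing: the source reports confidence intervals without
specifying their method, so we provide generic case-resampling percentile
intervals over traces rather than claiming a reproduction.

## Aggregate domain rates

What an experimentalist reads off a trace is not an elementary rate but an
*aggregate* one: the inverse mean dwell in a group of states.
`predict_aggregate_rates()` simulates one exact sample path (default
20,000 ms) from the fitted generator, merges sojourns into dwells in the
LID-open versus LID-closed (`M2*, M2**, M3**`) groups, censors the first
and last dwell (they do not end in an observed transition), and reports
inverse mean completed dwells: closing from the open group, opening from
the closed group; NMP analogues likewise (`M1, M1*, M1**, M3**` closed).
A group with no completed dwell (e.g. an absorbing open group) yields
`NA`, flagged by the dwell counts.

## The synthetic generator and the reference parameterization

`simulate_experiment()` replaces the original recordings: per condition it
samples a CTMC path (exponential sojourns, jump-chain targets), with the
initial state drawn from the stationary distribution at that condition
(mirroring the likelihood's prior), discretizes it on the 0.2 ms grid and
adds independent Gaussian noise per sample. The default design is the six
ATP/AMP concentration pairs (0.01/0, 0.1/0, 1/0, 1/0.01, 1/0.1, 1/1 mM)
with three replicates (within the reported two to four) of 2000 ms each —
within the reported 500-10,000 ms range, chosen fixed for tractable
simulation sizes; `adp_design()` gives the seven-point ADP titration.
`inject_artifacts()` overwrites stretches with open-pore (~ -433 pA) or
shallow (>= -160 pA) noise to exercise segment selection.

The elementary rates of the original model are published only in a figure
not reproduced here, so `rate_vector()` carries a *reference
parameterization* constructed from the printed aggregate observations: an
association slope of 2.2 uM^-1 s^-1, binary- and ternary-complex LID
opening of 693.4 and ~120 s^-1, aggregate LID closing near 1000 s^-1 at
saturating ATP, NMP closing near 200 s^-1 (`b2 = 200`), M3 exit 3.4e3
s^-1 (`bm2`), and the apo NMP excursion rates 4.7/55.2 s^-1 (`b1`/`bm1`).
Specifically, with the LID closing attempt `r1` and the unbinding rate
`km1` competing from `M*`, the low-concentration closing slope is
`k1 * r1 / (r1 + km1)` and the saturating aggregate closing rate is
`1 / (1/(k1 C) + 1/r1)`-like; solving those two constraints at the
printed values gives `r1 ~ 1800` and `k1 ~ 4600 mM^-1 s^-1` for a chosen
`km1 = 2000 s^-1`. M0 exchange rates make the shallow excursions sporadic
(entry ~1 s^-1) and brief (exit ~200 s^-1 total). This parameterization is
synthetic — a consistent stand-in, not the published estimate — and is the
generating truth for the package's simulate-and-refit checks.

What the generator deliberately does *not* emulate: the amplifier chain
(10 kHz Bessel + 2 kHz Gaussian filtering) that colors real noise —
emissions are white, matching the conditional-independence assumption of
the likelihood itself — and multi-enzyme series with molecule-specific
level offsets (per-trace offsets in the fit cover the mechanism, but the
true offset distribution is unknown). Passing tests therefore demonstrate
correctness of the estimation machinery under the model's own
assumptions, not robustness to correlated noise or heterogeneous
molecules.

## Event-level analysis

`select_segments()` screens traces with a 50 ms sliding-window mean (the
source gives only the cutoffs, not the window; 50 ms is long against the
sub-ms kinetics and short against artifact durations), keeping runs
strictly between the open-pore exclusion cutoff (-350 pA; "around -400 pA"
excursions are comfortably below it) and the shallow cutoff (-160 pA).
`pick_fit_segments()` draws one random segment per condition and
right-truncates all of them to the least of the shortest selection and
1000 ms. `all_point_histogram()` uses 0.1 pA bins anchored at 0 pA so bin
edges are reproducible; level occupancies are computed from fitted peak
*heights* (counts at the maxima, not areas). `idealize()` implements
half-amplitude threshold crossing between adjacent configured levels with
minimum-duration merging (0.1 ms floor for level events, 1 ms for blockade
classes) — the vendor "single-channel search" is undocumented, and this is
the standard single-channel equivalent, with fixed rather than adaptive
thresholds. Dwell-time rates come either from a least-squares single
exponential on dwell histograms binned near the expected dwell, or
directly from the sample mean (the exponential MLE).

## Dose-response fits

`hill_fit()` fits `y = y_max c^n / (K_D^n + c^n)` (increasing) or a
decreasing form with a floor `y_min` — opening frequencies plateau at a
nonzero rate, hence the floor; the decreasing parameterization is our
choice where the source says only "Hill function". `y_max` floats by
default (whether it was fixed at 100% is not stated). Starts are
deterministic (`K_D` at the geometric mean concentration, `n = 1`) so fits
reproduce without global search. This module works in uM (dissociation
constants are reported in uM); `um_to_mM()`/`mM_to_um()` convert to the
generator's mM. `linear_fit()` (closing frequencies), a one-site specific
binding fit (Mg2+ dependence), and the two-state steady-state check
`100 k_on C / (k_on C + k_off)` complete the module.

## Numerical choices and degenerate inputs

* Matrix exponential: scaling-and-squaring (Armadillo); verified against a
  high-order scaled Taylor series to 1e-10 on well-conditioned 10x10
  generators.
* Stationary law: bordered linear solve of `delta' Gamma = delta'`; for
  ill-conditioned chains a repeated-squaring fallback (rows of `Gamma^(2^k)`
  converge for any aperiodic unichain). A chain with more than one
  recurrent class is rejected as having no unique stationary law; chains
  with transient states (e.g. zero AMP, unreachable ternary states) are
  fine.
* Likelihood failures at absurd parameter values (underflow to zero mass)
  return `-Inf` and are handled by the optimizer as a large penalty.
* Idealization merges sub-threshold events into the preceding event
  (first event merges forward) until stable — deterministic tie-breaking.
* Sampling a sojourn shorter than `dt` that straddles no sampling instant
  leaves no sample: aliasing inherent to discrete sampling, documented in
  `discretize_path()`.

## Problem sizes used by the checks

The package's own verification runs use reduced but representative sizes,
chosen to exercise every code path at meaningful statistical depth: the
simulate-and-refit check uses the six ATP/AMP conditions at one 1000 ms
segment each (the same one-segment-per-condition, <= 1000 ms rule used for
the original estimation), six multistarts; model selection uses two
conditions at 800 ms; dwell and occupancy oracles use 20-200 s paths of
two- and three-state chains, where exact closed forms exist. The
two-state toy (open/closed pore, known rates) recurs throughout because
every aggregate quantity has an analytic value there.

## Known limitations

* Emission noise is white; no Bessel/Gaussian filter emulation (an
  avenue, not a default, since the likelihood assumes independence).
* No Baum-Welch/EM and no Viterbi decoding: the likelihood is maximized
  directly, filtered probabilities are optional plumbing.
* Bootstrap intervals are generic plumbing, not the original
  (unspecified) interval method.
* No Hessian standard errors or profile likelihoods.
* The Ap5A-bound fully-closed state (M4), alternative whole-protein
  blockade types, and explicit Mg2+ states are out of scope; Mg2+
  presence is carried as metadata only.
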