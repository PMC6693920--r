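---
title: "Models and methods in driftchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in driftchoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling problem

`driftchoice` models joint choice and reaction-time (RT) data from
two-alternative decisions. Two task families are supported:

* **Value-based decisions**: a participant chooses between two familiar
  items whose subjective values were elicited beforehand (dollar
  willingness-to-pay on a $0–3 auction scale, or 0–10 preference ratings
  z-scored within participant). The stimulus strength of a trial is
  ΔValue, the value of the right item minus the left item.
* **Perceptual decisions**: the participant judges whether a flickering
  dot display is predominantly blue or yellow. Strength is the signed
  color coherence `C = log(p_blue / p_yellow)`, drawn from 11 fixed
  levels between −2 and 2; each dot is blue with probability
  `plogis(C)`.

Both tasks produce the same data shape — a signed strength, a binary
choice, an RT, and a validity flag — so one model applies to both.

## The bounded drift-diffusion model

The decision variable accumulates noisy evidence from `x = 0`:

    dx = mu * dt + N(0, dt)

The diffusion coefficient is fixed at 1; every evidence-scale parameter is
defined relative to it, which removes the familiar scale degeneracy of
diffusion models. Drift depends on strength `s` through a power law,

    mu = kappa * sign(s) * |s|^plaw + mu0

so that `plaw = 1` recovers the linear drift model and `mu0` absorbs a
left/right (yellow/blue) bias. The symmetric absorbing bounds sit at
`±B(t)`, with

    B(t) = B0                          for t <  Bdel
    B(t) = B0 * exp(-(t - Bdel)/B2)    for t >= Bdel

a collapsing bound, the normative shape when difficulty is mixed across
trials: it implements mounting urgency and produces the slower errors
seen in data. RT is decision time plus a Gaussian non-decision time with
mean `tnd` and sd `sigma_tnd`, truncated at zero and renormalized
(negative latencies are unphysical; the truncation point is a package
choice, the source model is silent about it).

### Units and typical magnitudes

| parameter | units | typical fitted range |
|-----------|-------|---------------------|
| `kappa` | 1/(evidence-unit^plaw · s) | 0.5 – 10 |
| `B0` | evidence units | 0.5 – 2.5 |
| `Bdel` | s | 0 – 1 |
| `B2` | s | 0.1 – 5 |
| `tnd`, `sigma_tnd` | s | 0.3 – 0.8, 0.02 – 0.2 |
| `mu0` | 1/s | about 0 |
| `plaw` | – | 0.5 – 1.5 |

## First-passage densities

The likelihood of a trial is the RT density of the chosen bound at the
observed RT. `solve_first_passage()` obtains these densities by
propagating the Fokker–Planck equation with a fast convolution scheme:
the density over evidence is advanced one time step by convolution with
the Gaussian transition kernel (mean `mu*dt`, variance `dt`), and the
mass in the part of each grid cell beyond the current bound is absorbed
into that step's first-passage mass.

Numerical choices that matter:

* **Continuity correction.** Discrete-time absorption misses within-step
  excursions beyond the bound, which biases the effective bound upward by
  about `0.5826 * sqrt(dt)` (the Broadie–Glasserman–Kou constant from the
  theory of discretely monitored barriers). The solver shrinks the
  applied bound by exactly that amount. With the correction, flat-bound
  choice probabilities and mean decision times agree with the closed
  forms `P(upper) = 1/(1 + exp(-2*mu*B0))` and
  `E[T] = (B0/mu) * tanh(mu*B0)` to ~0.03% at the default grid — without
  it, mean-time errors are ~2%.
* **Grids.** Default `dt = 0.5` ms with at least 200 evidence points
  spanning `[-B0, B0]` (`dx` also capped at `0.75*sqrt(dt)` so the
  one-step kernel is resolved; a coarser `dx` raises an error rather
  than returning an inaccurate answer). Fitting uses a coarser grid
  (`dt = 2.5` ms, 96 points) whose closed-form errors (~0.1–0.2%) are far
  below likelihood noise at realistic trial counts; the grid-refinement
  invariant is tested at the default resolution.
* **Conservation.** The transition kernel is renormalized so each step
  conserves mass exactly; absorbed + surviving mass is checked against 1
  (tolerance 1e-3).
* **Survivor mass** at the horizon is ignored by the likelihood: missed
  trials are flagged invalid and excluded, matching the treatment of the
  behavioral data, and the likelihood of responded trials is not
  renormalized.
* **Likelihood floor.** Per-trial densities are clipped at 1e-10 before
  taking logs. Without a floor a single implausible RT drives the
  objective to infinity and strands the simplex search; the floor value
  is a robustness choice, not a statement about the data.

The Euler–Maruyama simulator (`simulate_ddm_trials()`, step 0.1 ms) is a
deliberately separate implementation of the same process — a path-level
Monte-Carlo oracle sharing no density code with the solver. The test
suite requires the two routes to agree in choice probability and RT
deciles. Decile tolerances include a `0.5826*sqrt(dt_sim)` term: the
plain simulator has exactly the discretization bias that the solver
corrects for, and that allowance comes from the same theory (declared
before the comparisons were run, not tuned to them).

## The heuristic alternative

The rule-based alternative model classifies each item by two criteria
`kappa1 <= kappa2` into highly undesirable (D−), middling (D≈) and
highly desirable (D+); values exactly on a criterion fall in D≈ (an
inclusive-middle tie-break, so the criteria remain strict thresholds).
Pairs where the rules force a side — D+ against anything, D≈ against D−
— are *trivial*: fast (Gaussian RT with mean `mu_fast`) and
near-deterministic. Same-category pairs are *non-trivial*: slow
(`mu_slow`) with choices following a logistic in ΔValue. Because the
trivial rule is deterministic but real choices are not, rule-consistent
trivial choices get probability 0.99 during fitting (the
"trembling-hand" variant frees this probability instead, adding one
degree of freedom: 9 vs 8, the fixed variant matching the diffusion
model's 8 so BIC comparison reduces to deviance). For model-comparison
statistics the 0.99 penalty is replaced by the fitted logistic evaluated
at the dataset's maximum |ΔValue| (`mode = "bic_eval"`); the package
reports both likelihoods rather than taking a side on an acknowledged
ill-posedness. RT Gaussians are evaluated without deadline truncation,
as specified.

## Fitting and model comparison

`fit_ddm()` and `fit_heuristic()` minimize the joint negative
log-likelihood with multi-start Nelder–Mead. Box bounds (generous
margins around published best-fit magnitudes) are enforced by a logistic
reparameterization so the simplex itself is unconstrained; starts are
drawn uniformly in the box from a seeded RNG, making fits exactly
reproducible given `(seed, n_starts)`. All starts run under a capped
iteration budget and the best few are refined with repeated Nelder–Mead
restarts (a fresh simplex at the incumbent) until a restart stops
improving the objective — the standard screen-then-polish economy, with
restarts because a collapsed simplex otherwise stalls partway down the
long curved valley that couples `kappa`, `B0` and `tnd`. `sigma_tnd` is bounded away from
zero (at 1 ms) because at exactly zero the interpolated likelihood
degenerates into a comb of grid spikes.

Reduced variants: `no_plaw` fixes `plaw = 1`; `no_plaw_flat_bounds`
additionally disables the collapse by pushing `Bdel` past the horizon
(5 free parameters). Fits are compared with
`BIC = 2*nll + k*log(n)`; `bic_compare(a, b)` returns `BIC_b − BIC_a`,
which for equal `k` is exactly the deviance difference. Goodness of fit
is summarized by the McFadden pseudo-R² for choices against the
intercept-only Bernoulli null, and an R² over per-level mean RTs.

For grouped fits of dollar-scale data, ΔValue is first rounded to $0.10
(fewer distinct drift rates; not applied to z-scored values, where a
dollar step has no meaning) and binned into 11 fixed-edge levels
whose targets are the coherence set scaled to the observed ΔValue range
— the intent being parity with the discrete perceptual levels. Exact
edge placement is not specified by the source description; this is the
package's choice, and conclusions that depend sensitively on the edges
(e.g. small BIC differences between nested variants on binned data)
should be checked against the unbinned fit. Trials exactly on an edge
go to the upper bin; empty bins are dropped with a warning, each level
is represented by the mean ΔValue of its members.

## Synthetic data: what the generator states, and what it does not

The generator reproduces the *structure* of the two tasks exactly:

* 60 items, each appearing in exactly 5 of 150 unique pairs; 90 pairs
  shown once and 60 twice (each item gaining exactly 2 extra
  appearances), 210 trials in 3 runs of 70, higher-value side
  counterbalanced 105/105. The pairing is a circulant scheme over the
  value-rank circle (offsets 1, 7, 30), so ΔValue spans adjacent-rank to
  opposite-half differences; the repeated pairs are the adjacent-rank
  ones. Any scheme satisfying the count invariants is admissible — the
  original stratification is unstated — and this one is deterministic
  given the seed.
* 210 perceptual trials drawn near-uniformly from the 11 coherence
  levels.
* Dot frames at the stated aperture (5 cm), density (16.7 dots·cm⁻²·s⁻¹)
  and frame rate (60 Hz), for stimulus-level sanity checks only.

Item values are drawn uniform on $0–3 rounded to cents (the auction
scale; the true distribution of bids is unstated) or as integer 0–10
ratings that are z-scored. Inter-trial intervals are not generated; they
do not enter a behavior-only pipeline.

The default synthetic cohort (`default_cohort_spec()`) is 14 "healthy"
and 6 "amnesic" diffusion agents — the group sizes of the
patient/control comparison — with the impaired group given a shallower
drift scale (kappa 0.8 vs 2.0), a higher, later-collapsing bound and a
longer non-decision time (0.8 s vs 0.45 s). These values were chosen
once to produce the qualitative impairment signature (flatter choice
function, roughly doubled RTs, clearly lower efficiency index) at a
plausible magnitude; they are a stated world, not a fit to any dataset.
A green end-to-end test therefore establishes that the pipeline detects
a *configured* group difference of this size with the study's group
sizes — not that the real patient effect has this size, and not that
real data were reproduced. Real behavior also contains features the
generator omits entirely: sequential dependencies, lapses, fatigue,
value drift between rating and choice, and deadline-censoring dynamics
beyond a hard cutoff.

Heuristic agents have no defined perceptual behavior (the model is a
value-categorization rule); when a cohort requests perceptual tables
from heuristic agents the generator substitutes a logistic-in-coherence
choice with slow-Gaussian RTs, which should be treated as filler, not
model output.

## Efficiency index and group statistics

`score_trials()` scores a choice 1 when it matches the higher value (or
the coherence sign), 0 otherwise, 0.5 when ΔValue or coherence is
exactly zero — the zero-strength convention extended symmetrically to
value ties. `efficiency_index()` is per-participant mean score divided
by mean RT over valid trials (zero-strength trials included; exclude
them upstream if the other convention is wanted). Group differences use
`welch_t()`, written out from the Welch–Satterthwaite formulas and
checked against `stats::t.test` to 1e-10.

## Known limitations

* No starting-point variability, drift-rate variability, or asymmetric
  bounds — the modeled process does not include them.
* The published grouped-fit BIC values cannot be reproduced without the
  deposited trial-level data; the comparison machinery is exercised on
  synthetic stand-ins only (see the acceptance notes).
* Fitting grouped data with binned ΔValue inherits the bin-edge choice
  described above.
* The heuristic model's trivial-choice penalty makes its absolute
  likelihood (and hence BIC) convention-dependent; both conventions are
  computable, neither is privileged.
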