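---
title: "Structured trophic interaction modifications: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured trophic interaction modifications: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timweb)
```

## The question

Large random interaction networks tend to be locally unstable, and much of
network ecology asks which structural features of real communities mitigate
that. Higher-order interactions (HOIs) — terms in a species' growth rate that
involve the product of two or more *other* species' abundances — have been
proposed as a generic stabilising feature, but that conclusion rests on
assuming the HOIs are randomly distributed: many zero-centred terms summed
over many dimensions tend to cancel. Trophic interaction modifications
(TIMs), in which a modifier species changes the strength of a
consumer-resource link (predator avoidance, associational defence, foraging
switches), are a biologically grounded class of HOIs that are *not* random:
they are anchored to the trophic network and often carry systematic signs.
`timweb` implements a simulation pipeline for asking what structured TIM
distributions do to (i) community-matrix structure, local stability and
feasibility, and (ii) the diversity-stability relationship under explicit
higher-order Lotka-Volterra dynamics.

## Synthetic communities

Everything is generated in-package; there are no external data.

**Topology.** `generate_niche_web(S, C_target)` draws a niche-model web:
niche values uniform on (0, 1), feeding range `n_i * x` with
`x ~ Beta(1, 1/(2C) - 1)` (calibrated so the expected directed connectance
`L/S^2` equals `C_target`), feeding centre uniform on `[r/2, n]`. The default
study condition is `S = 60`, `C_target = 0.2` — a moderately large,
well-connected community. Conventions the niche-model literature leaves to
the implementer, fixed here once: the smallest-niche species is forced basal;
self-links arising from the niche interval are removed (self-regulation is
handled separately at matrix assembly), which makes the estimator's exact
expectation `C(1 - 1/S)`; duplicated niche values are resampled; webs with an
isolated species, more than one weak component, or realized connectance more
than 15% (relative) from target are regenerated, up to 1000 attempts.
Rejection keeps the per-species TIM frequency comparable across replicates.

**Strengths.** Each link draws a correlated pair from a bivariate Gaussian:
consumer-on-resource effect `N(-1, 0.5)`, resource-on-consumer effect
`N(+1, 0.5)`, correlation `-0.8`, matching empirical interaction-strength
patterns in sign and asymmetry. Draws are not truncated: a rare positive
consumer-on-resource draw is allowed, as the distribution implies. When a
pair of species eat each other (rare but possible in the niche model), the
two links' linearized contributions add in the shared cells.

A point worth spelling out because it is easy to conflate: the **generating
correlation** of `-0.8` is between *role-ordered* effects. The matrix-level
statistic `pairwise_correlation()` instead pools reciprocal cells
symmetrically, mixing the two role clusters centred at `(-1, +1)` and
`(+1, -1)`; for the default parameters its trophic-only baseline is

$$\frac{\rho\,\sigma^2 + \mu_{RC}\,\mu_{CR}}{\sigma^2 + (\mu_{RC}^2 + \mu_{CR}^2)/2} = \frac{-0.2 - 1}{1.25} = -0.96,$$

more negative than `-0.8`. Both conventions are exercised in the tests; the
package reports the pooled statistic as the structural metric (it requires
no role bookkeeping once non-trophic effects blur the roles) and uses the
role-ordered correlation for parameter recovery.

## TIM distribution models

A TIM is a triple (resource `i`, consumer `j`, modifier `k`) with a signed
strength `c_ijk`; `(j, i)` must be a trophic link and `k` a third species
(species do not modify their own interactions). Seven distribution models
place TIMs relative to the web (`tim_models`): `random`;
`nearby_only`/`far_only`, which condition on the modifier being trophically
linked to an interactor or not (the two partition the random candidate set);
`facilitating`/`interfering`, which force the sign positive or negative;
`reciprocal`, which introduces TIMs in tight pairs (k modifies j's
consumption of i, and i in turn modifies j's consumption of k — two
resources of a shared consumer); and `mutual_interference`, the reciprocal
topology with both signs forced negative, representing foraging choices
where each resource reduces consumption of the other.

Sampling (`sample_tim_set()`) is uniform *without replacement* over the
candidate set — a triple occurs at most once, and the additive-combination
rule below applies to distinct TIMs sharing a cell. For the paired models,
pairs are atomic and each member counts toward the per-species frequency
`lambda`, so the count is `round(lambda * S)` rounded to the nearest even
number; the two members draw magnitudes independently. Strengths are
`N(0, alpha * sqrt(pi)/sqrt(2))`, making the mean magnitude exactly `alpha`
(half-normal mean); `alpha = compute_alpha(B)` is half the mean absolute
trophic strength, in line with meta-analyses placing non-trophic effects at
the same order as, but weaker than, trophic ones.

Each TIM linearizes into exactly two non-trophic effects (NTEs): `+c` from
modifier onto consumer, `-c` onto resource (`build_nte_matrix()`), so every
TIM is sign-balanced by construction and the NTE matrix sums to zero.
Overlapping effects add. The benchmark `random_nte_baseline` scatters the
matching number of NTEs (two per TIM) over uniformly chosen distinct
off-diagonal cells. Note this baseline saturates: at `S = 60` and
`lambda = 30`, 3600 effects exceed the 3540 off-diagonal cells, so the
baseline's top frequency is structurally unreachable and the drivers record
that condition as a per-row failure rather than silently capping it.

## Matrices, stability, feasibility

`assemble_community(B, C, diagonal)` sums trophic and non-trophic matrices
off the diagonal and writes the self-regulation value on the diagonal.
Structural metrics (`structure_metrics()`) use population (divide-by-n)
variance and covariance over all off-diagonal cells, zeros included — the
matrix-ensemble convention of the random-matrix stability literature.
Degree heterogeneity pools each species' in- and out-degree into one
2S-vector normalised by its mean ("normalised in and out-degree
distribution" admits several readings; this one is adopted and tested).
Zero-vs-nonzero is an exact comparison: entries are either structurally zero
or continuous draws, so no epsilon is warranted; exact cancellation by
additive NTEs counts as zero.

**Local stability** is `Re(lambda_1)` of `A` with the diagonal forced to
zero: without self-regulation the leading real part is non-negative and
measures how much uniform self-regulation would stabilise the system;
`instability_score()` is its natural log.

**Feasibility** is the orthant probability `Omega(A)` that a uniformly
random growth-rate direction yields an all-positive equilibrium, computed
as the positive-orthant mass of a centred Gaussian with covariance
`solve(crossprod(A))` via the Genz-Bretz quasi-Monte-Carlo algorithm
(`mvtnorm::pmvnorm`, absolute tolerance `1e-4`, fixed internal seed so
results are reproducible call-to-call); the per-species size is
`omega = Omega^(1/S)`. Exact integration is infeasible at `S = 60`; the
implementation is validated against the analytic identities
`omega(-dI) = 0.5`, scale invariance, the bivariate closed form
`1/4 + asin(rho)/(2*pi)`, and an independent sphere-sampling Monte-Carlo
oracle (`mc_feasibility()`). Feasibility depends non-trivially on
self-regulation, so it is evaluated at a default diagonal of `-2` with `0`
and `-5` as sensitivity settings; matrices with condition number above
`1e12` are refused and logged rather than returning a silent zero.

## Higher-order dynamics

The dynamical model is per-capita Lotka-Volterra with explicit
self-regulation and interaction arrays of orders 2-4:

$$\frac{1}{x_i}\frac{dx_i}{dt} = r_i - x_i + \sqrt{\alpha}\sum_j A_{ij} x_j + \sqrt{\beta}\sum_{jk} B_{ijk} x_j x_k + \sqrt{\gamma}\sum_{jkl} C_{ijkl} x_j x_k x_l,$$

with `r_i = 1/N`. Random arrays are standard normal with every
repeated-index entry zeroed (self-regulation is its own term; allowing
self-referential interaction entries would double-count it). **All**
interaction arrays — random or structured — are scaled to unit population
variance over *all* elements before the square-root strength scalers apply.
This whole-array convention matters: it is what makes arrays of different
sparsity exert comparable aggregate strength, so a sparse structured tensor
receives proportionally larger entries. (Normalising over nonzero entries
instead would leave sparse ±1 tensors untouched, make connectance
irrelevant to the scaling, and change the diversity trends qualitatively.)

Structured tensors are built from mutual-interference TIMs sampled at a
frequency of `0.1 N^2` on the same niche web that underlies the pairwise
baseline (the TIMs must reference real shared-consumer pairs): each TIM
writes `+1` at `[i, j, k]` and `-1` at `[j, i, k]`, and, for the 4-way
tensor, each admissible fourth species is activated with probability 0.1,
inheriting the parent's sign (whether the original construction re-drew the
sign is unstated; inheritance is the assumption made here). Collisions add.
The trophic pairwise baseline is used at a fixed small `alpha = 0.001` with
element variance further scaled by `1/sqrt(N)`.

**Simulation.** Communities start at `x_i = 1/N` and integrate with
`deSolve::lsodar` under three root conditions: extinction (any species below
`1e-4/N`), steady state (`max |dx_i/dt|/x_i < 1e-9`), divergence (any
abundance above `1e3`, far outside the `O(1/N)` plausible range, classified
infeasible — strong 3-/4-way positive feedback can blow up in finite time).
The horizon `t_max = 500` counts as feasible if neither extinction nor
divergence occurred; the model itself implies no particular horizon or
tolerance, so these are package choices, fixed once and stated here.
Integrator tolerances are `rtol = 1e-8`, `atol = 1e-12/N` (the extinction
threshold is `1e-4/N`, so absolute error must resolve well below it).

**Critical strength** (`critical_strength()`) is the highest strength of the
varied scaler at which strictly more than 90% of independently drawn
communities persist with no extinction: a 12-point log-spaced sweep across
four decades (`10^-3..10` for pairwise, `10^-2..10^2` for higher orders),
then 8 bisection steps in log space between the last passing and first
failing strengths. Batches stop early once the >90% verdict is settled,
which is why recorded `n_run` can be below `n_total`. A monotonicity audit
checks that the feasible fraction does not increase along fully evaluated
sweep points; ties and partial batches are recorded rather than hidden.

## Reproducibility and problem sizes

Every driver takes one master seed and derives a child seed per sub-task
(web, condition, community replicate) through a fixed affine map, recorded
in the output row, so any single condition can be regenerated in isolation.
Reruns with the same seed produce byte-identical CSVs.

The full study design — 100 webs by 8 models by 16 TIM frequencies, and
50-community batches on fine strength grids — is a batch-scale computation.
The package's own test suite exercises the same pipeline at sizes chosen to
be statistically meaningful per check: 100 webs for connectance recovery,
at least 10^4 link draws for strength recovery, 10 webs at `S = 60` and
`lambda` in {0, 10, 20, 30} for the structure/dynamics directions, and
20-community searches at `N` in {10, 20, 30} on the reduced (`quick`) grid
for the diversity-stability directions, asserted as rank orderings rather
than values.

## What the generators do and do not emulate

The synthetic communities reproduce the topological regularities of the
niche model, empirically signed and correlated pairwise strengths, and
sign-balanced TIM-induced NTEs at a calibrated magnitude. They do not
attempt: empirical interaction-strength distributions (real webs are closer
to log-normal, with strong row structure), modifications of non-trophic
interactions (only trophic links are modifiable here), unbalanced NTE pairs,
non-uniform self-regulation, or empirical food-web topologies. Passing tests
therefore demonstrate internal correctness of the pipeline and the
robustness of the qualitative contrasts between TIM distribution models
within this generative world, not quantitative predictions for any real
community.

## Known limitations

- The orthant computation returns an absolute-tolerance estimate; for
  matrices whose `Omega` is far below `1e-4` only `omega = Omega^{1/S}` is
  meaningfully resolved, which is the quantity used throughout.
- The critical-strength search assumes an essentially monotone
  feasibility-strength relation; the audit flags violations but the search
  does not globally optimise.
- `lsodar` event detection locates threshold crossings to integrator
  precision; an extinction threshold crossed and re-crossed between steps
  could in principle be missed at loose tolerances (the defaults are far
  tighter than that regime).
- At `S = 60` the `random_nte_baseline` cannot represent `lambda = 30`
  (cell capacity), so baseline comparisons there end at `lambda = 28`.
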