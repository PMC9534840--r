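---
title: "Fitting the continuum circle model to grooming ego-networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting the continuum circle model to grooming ego-networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groomcircles)
```

## The model

An ego-network is the set of relationships around one focal individual,
each carrying an investment (here: grooming effort) `s_i`. Two widely
accepted assumptions — the ego's total social capital is finite, and more
intense relationships cost more of it — lead, via maximum entropy, to an
exponential allocation of relationships over cost levels.

In the **discrete** formulation there are `r` cost categories
`s_max = s_1 > … > s_r = s_min` and the probability that a relationship
belongs to category `k` is `p_k ∝ exp(-μ̂ s_k)`, with the Lagrange
multiplier `μ̂` fixed by the mean cost. Writing
`μ = μ̂ (s_max − s_min)/(r − 1)`, the expected fraction of relationships
at cost at least that of category `k` — the cumulative circle size — is
`χ_k = (e^{kμ} − 1)/(e^{rμ} − 1)` (`circle_sizes()`). For large `μ`
consecutive circles scale by `e^μ`; `μ ≈ 1` reproduces the classical
factor of about 3. For `μ < 0` the ratio tends to 1: the "inverted"
regime where most relationships sit in the innermost circle.

The **continuum** formulation replaces categories by a normalized cost
`t ∈ [0, 1]` (`t = 0` the most intense relationship, `t = 1` the least)
and a single scale parameter `η`:

$$\chi(t) = \frac{e^{\eta t} - 1}{e^{\eta} - 1},$$

the fraction of relationships with normalized cost at most `t`
(`continuum_cdf()`). The regime boundary is `η = 0` (uniform allocation).
The two formulations are connected twice over, and this is a place where
the design was genuinely open:

* the *exact* algebraic identity `χ(k/r; η = rμ) = χ_k(μ, r)`
  (`eta_from_mu_exact()`), and
* the *approximate* correspondence `η ≈ (r − 1)(e^μ − 1)`
  (`eta_from_mu()`), obtained by matching the discretized logarithmic
  derivative of `χ` with layer spacing `Δt = 1/(r − 1)`.

At `r = 4`, `e^μ = 3` these give `4 ln 3 ≈ 4.39` and `6` respectively.
We expose both and default to the approximate form, because it is the one
used to translate fitted `η` values into per-layer scaling ratios; its
accuracy is what one expects of a first-order matching — the discretized
log-derivative agrees with the continuum one to within about 20% over
`μ ∈ [0.5, 1.5]` (the package asserts that bound in its tests).

## Estimation

For an ego with weights `s_1, …, s_L` we take `s_max` and `s_min` from
the ego's own data, set `σ = mean(s_i)`, and form
`t_i = (s_max − s_i)/(s_max − s_min)` (`normalize_costs()`). Both
extremes are included in the mean — the model averages over all `L`
relationships, and dropping the anchoring extremes would bias `t̄`.
(The convention is the cost one: the most-groomed alter is `t = 0`. The
empirical step points of `empirical_cost_cdf()` follow the same
convention, with tied weights grouped into a single step so the result is
a proper cdf.)

The normalized costs are modeled as iid draws from
`p(t) = η e^{ηt}/(e^η − 1)`, a one-parameter exponential family with
natural statistic `t`. Maximizing the likelihood is therefore exactly
moment matching:

$$\bar t = \mathbb{E}[t;\eta] = \frac{e^{\eta}}{e^{\eta}-1} - \frac1\eta,$$

and since `E[t; η]` is strictly increasing, the ML estimate is the unique
root, found by `solve_eta()` (bracketing `uniroot`, bracket `[-50, 50]`
doubled outward as needed, absolute tolerance 1e-10). The tests verify
the ML/moment equivalence independently by grid search of the
log-likelihood.

**Confidence intervals.** We use a Wald interval on the mean:
`t̄ ± z_{1−δ} √(Var[t; η̂]/L)` with the exponential-family identity
`Var[t; η] = dE[t]/dη = 1/η² − e^η/(e^η − 1)²`, mapped through the
strictly increasing inverse `η(t̄)`; `δ = 0.025` gives the nominal 95%
level. The construction is monotone, so the interval always contains
`η̂`, and the `χ(t)` confidence band of `fit_band()` is simply the
envelope `[χ(t; η_high), χ(t; η_low)]`. A percentile bootstrap over
alters (`eta_confint_boot()`) is provided as a cross-check. Calibration
was chosen over elegance here: in seeded simulations at `η = 4`,
`L = 50`, the Wald interval covers the truth in about 95% of 1000
replicates (asserted in the acceptance tests; the true `η` of that study
is a package choice — the modal value the study design centers on — since
only the level `δ` is prescribed). Two caveats are worth knowing: on the
`η` scale the width follows the CLT `1/√L` rate only once `L` is
moderate (at `L = 10` the curvature of the inverse map inflates it), and
the *relative* precision of `η̂` degrades as `η → 0` because
`se(η̂) ≈ 1/√(L · Var[t;η])` stays of order `12/√L` while the target
shrinks — at `L = 500`, `η̂` for a true `η = 0.5` is precise to about
±0.16, i.e. ±31% relative.

**Regimes and refusals.** Fits are labeled `normal` (`η̂ > 0`) or
`inverted` (`η̂ < 0`), with `boundary` when the interval straddles 0.
Egos below the partner threshold are refused by `fit_ego()` outright;
degenerate inputs (all weights equal, so `s_max = s_min`) produce a
flagged record with no fitted value rather than an arbitrary number.

## Curation rules

The curation defaults implement the standard focal-follow protocol
(10-minute follows, 10 instantaneous scans):

* follows lasting **5 minutes or less** are discarded with their events
  (visibility-truncated follows; the boundary is inclusive, so a 6-minute
  follow stays);
* grooming is **binarized per follow**: within one follow a partner
  contributes at most 1 regardless of how many scans showed grooming.
  This unifies the criterion when bouts start or end outside the
  observation window. The alternative `minutes` mode sums bout minutes
  (one scan = one minute when explicit durations are absent) and is a
  configuration switch, binarization being the field's standard;
* weights aggregate over the **whole study period** (grooming the same
  partner in two follows on the same day counts twice — the unit is the
  follow);
* egos that groomed **fewer than five** distinct partners are excluded
  from fitting — five is the canonical innermost grooming circle in
  primates, and fits on fewer relationships are meaningless — but remain
  as alters, leaving every retained ego's network untouched;
* duplicate `(follow, scan, partner)` rows are collapsed with a warning
  (multi-observer entry noise); cross-group dyads are an error, since the
  study populations do not interact.

`run_pipeline()` chains these stages and keeps a reconciled count of what
each stage dropped (`n_egos_pre_filter = n_retained + n_excluded`, etc.).

## The synthetic generator

Real grooming observation datasets of this kind are typically shareable
only on request, so the package carries a generator
(`simulate_focal_observations()`) whose defaults are the study conditions
the pipeline targets: four non-interacting groups of 26, 60, 11 and 14
individuals; 300 full-length follows per individual (the order of a
multi-year observation effort); 10 scans per 10-minute follow; and per-ego
true `η` drawn log-normally with median 4 (`sdlog = 0.4`), the modal
scale reported for chimpanzee grooming networks, so all true values are
positive. Remaining knobs were fixed once at values a field researcher
would call realistic: a per-scan grooming probability of 0.2 (grooming
occupies a substantial minority of a chimpanzee's time budget), 5% of
follows drawn short (1–5 minutes) so the curation filter is exercised,
and latent extreme investments `s_max/s_min = 10/1` — only ratios matter
after normalization.

The observation model is per-scan categorical: each scan shows grooming
with probability `grooming_propensity`, toward one alter chosen with
probability proportional to the ego's latent rates
`s_i = s_max − t_i(s_max − s_min)`, with the `t_i` drawn from the model
density by inverse transform (`sample_costs()`,
`t = log(1 + u(e^η − 1))/η`). This makes the binarized per-dyad
expectation analytic — `1 − (1 − p_i)^{10}` per follow — which the tests
check against 2000 simulated follows.

What the generator does **not** emulate: fission–fusion spatial dynamics,
visibility bias, observer effects, demographic structure, or any
generative story linking grooming-time budgets to per-scan detection (the
categorical-scan model is our stand-in for the latter). Passing
end-to-end tests therefore show that the pipeline recovers the structure
it assumes from data shaped like scan-sampled follows — not that real
chimpanzee data satisfy those assumptions.

A consequence worth emphasizing, visible in `recovery_experiment()`
(pipeline mode): binarized counts are noisy, and because each ego's
normalization uses its *observed* extremes, count noise inflates the
range and compresses the interior `t` values, attenuating `η̂` downward
relative to the latent truth. The attenuation shrinks with sampling
effort, and it is strongest in small groups, where per-dyad scan
probabilities are large and per-follow hits saturate. This reproduces,
qualitatively, the expectation that small groups sit lower on the `η`
scale (more inverted-like structure) — but it also means a fitted
near-zero or slightly negative `η̂` can occur for an ego whose latent
`η` is positive. Noise-free recovery (`mode = "direct"`, fitting exact
draws from the density) is unbiased within Monte-Carlo error.

## Numerical choices

* `η = 0` is a removable singularity of every formula; below `|η| = 1e-6`
  we switch to second-order series (`χ(t) ≈ t + ηt(t−1)/2`,
  `E[t] ≈ 1/2 + η/12`) to avoid catastrophic cancellation, and the
  variance uses `1/12 − η²/240` below `|η| = 1e-3` where the direct form
  loses digits to cancellation of `1/η²`-scale terms.
* Large `|η|` is evaluated in factored form
  (`e^{η(t−1)}(1−e^{−ηt})/(1−e^{−η})` for `η > 0`; `expm1`/`log1p`
  throughout), so nothing overflows for `|η|` into the hundreds; discrete
  formulas at `μ = 0` return the exact limit `k/r`.
* `solve_eta()` returns exactly 0 when `t̄` is within solver resolution
  of 1/2; `t̄` at the domain boundary (0 or 1) is rejected as an
  infinite-`η` configuration, and CI endpoints are clipped just inside
  the domain, which caps the bounds at the solver bracket.
* Ties in the empirical cdf are grouped; order of input rows never
  affects curation output (asserted as a permutation-invariance test).

## Problem sizes in the test suite

The suite's simulation sizes are chosen to make the Monte-Carlo claims
sharp yet quick: distributional checks of the sampler at `n = 10⁴`–`10⁵`
draws; ML/moment equivalence on 20 samples against a 0.01-resolution
likelihood grid; parameter recovery at `L = 500` exact draws × 200
replicates per `η`; interval coverage at `L = 50` × 1000 replicates; and
one full four-group synthetic study (111 individuals, ~35,000 follows).
The whole suite runs in well under a minute.

## Known limitations

* The per-ego fit uses observed extremes; with few partners or few
  observations, `η̂` is attenuated (see above). Comparisons of `η`
  between datasets with very different sampling effort should use
  `recovery_experiment()` to gauge the expected attenuation first.
* The Wald interval is asymptotic in `L`; for `L` near the filter
  threshold of 5 it is wide and its coverage is not guaranteed — the
  bootstrap cross-check is recommended there.
* Group-level statements produced by `summarize_groups()` are
  descriptive; the package deliberately fits no hierarchical or
  covariate model (`η` is a per-individual quantity by construction).
* The histogram mode depends on the bin width (default 1.0 in `η`
  units); it is a display summary, not an estimator.
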