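---
title: "Methods: beta-Bernoulli prevalence estimation with administrative priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-Bernoulli prevalence estimation with administrative priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevbayes)
```

## The model and its assumptions

`prevbayes` estimates a single prevalence θ from a binary case flag
observed on n persons, k of whom are cases. The likelihood treats the
flags as independent Bernoulli(θ) draws — the identity parameterization
of a binomial-family model, so θ itself (not its logit) is the model
parameter. The prior is Beta(α, β), conjugate to the Bernoulli, so the
posterior is available exactly:

$$\theta \mid D \;\sim\; \mathrm{Beta}(\alpha + k,\; \beta + n - k).$$

The model assumes the flag is measured without error and the persons are
exchangeable; it deliberately does **not** model the sensitivity and
specificity of the instruments in the likelihood. A
misclassification-adjusted model is a natural extension, but it requires
either validation subsamples or strong external psychometric information,
and it changes the estimand from "prevalence of positive flags" to
"prevalence of the latent condition". The package keeps the simpler
estimand and instead exposes the misclassification machinery in its
synthetic-data generator, where the gap between true and apparent
prevalence can be studied with known ground truth.

## Prior elicitation

An informative prior is elicited from an external source with
`elicit_prior()`: α = k + 1, β = n − k + 1. Each observed case adds one
pseudo-success to a uniform Beta(1, 1) base, so zero information reduces
to the non-informative prior, and the prior mean (k + 1)/(n + 2)
approaches the raw proportion k/n at rate 1/n. The non-informative choice
is the uniform Beta(1, 1); Jeffreys' Beta(0.5, 0.5) is not offered — the
package standardizes on the uniform prior as its single
"no-information" reference, keeping the pseudo-count elicitation rule
and the flat prior mutually consistent. Priors carry a provenance label
so reports can cite the originating counts.

## The sampler

The posterior is one-dimensional and known in closed form, which makes it
an ideal target for a *checkable* sampler. `mcmc_sample()` runs adaptive
random-walk Metropolis on η = logit(θ): the target density picks up the
Jacobian dθ/dη = θ(1 − θ), giving

$$\log f(\eta) = -(\alpha + k)\,\log(1 + e^{-\eta})
                 - (\beta + n - k)\,\log(1 + e^{\eta}),$$

evaluated with `log1p` so it is stable for any counts. Gradient-based
samplers add nothing testable for a one-parameter conjugate model; the
random-walk chain, by contrast, can be validated draw-for-draw against
the exact Beta posterior, and that oracle agreement is the package's
central correctness property (asserted at 4 Monte-Carlo standard errors,
MCSE = posterior sd / √ESS-bulk).

Tunable settings (`mcmc_settings()`), with the defaults used by the
bundled preset:

* `iterations = 20000` per chain, **including** warm-up. The retained
  count is floor((iterations − warmup)/thin) = 3,900 per chain, 15,600
  pooled over 4 chains. We read "iterations" as the total per chain
  because the resulting retained-draw count is the smallest consistent
  with effective sample sizes in the 13,000–16,000 range that this kind
  of run produces — ESS cannot exceed the number of retained draws.
* `chains = 4`, `warmup = 500`, `thin = 5`, `seed = 123`. Each chain's
  RNG stream is seeded deterministically from (master seed, chain index),
  so runs are bit-reproducible and chains are distinct.
* `proposal_scale = 0.5` (initial, logit scale). During warm-up the log
  proposal scale follows a Robbins–Monro recursion toward the scalar
  random-walk optimum of 0.44 acceptance, with step size i^−0.6; the
  scale is frozen at the end of warm-up so the retained chain is a
  time-homogeneous Markov chain. Initial states are over-dispersed
  (θ₀ uniform on (0.05, 0.95) through the logit), which lets the
  diagnostics see non-convergence when warm-up is too short.

A chain that rejects every post-warm-up proposal raises a sampler-failure
error rather than returning silently degenerate draws.

## Convergence diagnostics

`convergence_report()` implements the modern rank-normalized forms of the
diagnostics. Draws are pooled, ranked (average ties), and mapped to
normal scores via Φ⁻¹((r − 3/8)/(S + 1/4)); each chain is split in half.
R-hat is √(((N−1)/N·W + B/N)/W) with W the mean within-half-chain
variance and B = N·var(half-chain means). Bulk ESS applies Geyer's
initial-monotone-positive-sequence truncation to the multi-chain
autocorrelation estimate of the rank-normalized split chains; tail ESS is
the minimum ESS of the indicators I(θ ≤ q₀.₀₅) and I(θ ≤ q₀.₉₅). ESS is
capped at the number of retained draws, and both statistics return `NA`
(treated as failure, with a reason) for degenerate chains.

The pass rule is R-hat ≤ 1.01 **and** bulk and tail ESS ≥ 1,000. The
ESS floor is the conventional reliability threshold; for R-hat, "1.0
means converged" and "1.05 means failed" bracket the choice, and 1.01 is
the strictest commonly used cutoff between them — with 15,600 retained
draws a well-mixed chain passes it comfortably, while the deliberately
short sensitivity run (80 retained draws) fails on both R-hat and ESS.
The classic non-split R-hat is intentionally not offered: it can pass
trending chains that the split form catches.

## Reporting conventions

Bayesian summaries are rounded to two decimals on the probability scale
and then printed as a percent with one decimal (0.5856 → 59.0%); the SE
column carries the posterior sd rounded to two decimals. The frequentist
row prints the percent to one decimal directly and its sampling SE to
three decimals. The Wald z-quantile is fixed at 1.959964 for bit-stable
intervals. These conventions are what `posterior_summary()`,
`frequentist_prevalence()` and the report table use; the underlying
unrounded numbers are always in the result columns.

## Ascertainment rules

Three interpretation decisions in the administrative case definition are
worth making explicit, because the rule's prose ("two or more outpatient
codes within a 24-month period") underdetermines them:

* **Sliding window, not calendar bins**: two outpatient dates qualify iff
  they are ≤ 730 days apart, regardless of where they fall in any
  calendar year. This is the stricter, order-free reading of "within a
  24-month period".
* **Distinct dates**: two claims billed on the same day are one visit,
  not a qualifying pair.
* **Inclusive boundaries, whole-day resolution**: the lookback is 1,826
  days (five years including one leap day) before study entry, inclusive
  at both ends; encounters after entry never count.

Linkage is deterministic (person id + date of birth); duplicates resolve
to the record with the higher completeness score, ties broken by earlier
enrollment date, then by cohort label A < B, so the merge is a pure
function of its inputs and idempotent. The self-report flag is an OR over
the instrument's mood and anxiety modules, missing only when every module
is missing. The mood modules reflect lifetime symptomatology while the
anxiety modules reflect the past month; this asymmetry is a data-semantics
caveat for interpretation, not something the OR computation can or should
correct.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the package's tests
and examples exercise: true prevalence 0.59; cohort sizes 1,061 and
2,369 with 272 duplicated enrollments (rate 272/1,061); instrument
completion 549/1,061, completely at random; self-report
sensitivity/specificity 0.95/0.84 (meta-analytic values for major
depression — the anxiety-instrument values 0.90/0.95 are similar, and a
single default pair keeps the generator simple); administrative coding
sensitivity/specificity 0.629/0.938 (validation values for
claims-derived depression diagnoses); five-year lookback; enrollment
windows 2011–2017 (cohort A) and 2018–2021 (cohort B).

The generator draws the person-level *intended* administrative flag first
(by sensitivity/specificity against the true status) and only then
materialises encounters: qualifying patterns for flagged persons (one
inpatient code, or an outpatient pair ≤ 730 days apart inside the
lookback) and strictly non-qualifying patterns for everyone else (nothing,
a single code, a pair > 730 days apart, or codes in an unrelated
diagnosis group). This makes the claims algorithm testable by round trip:
on any valid configuration, ascertainment must reproduce the intended
flags with zero mismatches. Note that the published misclassification
values come from external validation studies and are *not* jointly
consistent with an administrative case proportion near 59% at a true
prevalence near 0.59 (0.629·0.59 + 0.062·0.41 ≈ 0.40); the generator
therefore treats sensitivity/specificity as the primitive quantities, and
the analysis preset feeds the observed count table directly rather than
regenerating it.

What the generator does **not** emulate: informative missingness of the
instrument (completion is MCAR — nothing in the source material
identifies how non-completers differ), confounding between demographics
and outcome (demographics are cosmetic, drawn independently given case
status to hit the configured margins), repeat claims beyond the pattern
needed by the case rule, and real diagnostic code dictionaries (symbolic
`mood`/`anxiety`/`other` groups stand in for ICD chapters). Passing tests
therefore demonstrate the correctness of the algorithms, not the realism
of any particular claims-generating process.

## Numerical choices

Beta quantiles use the exact inverse CDF (`qbeta`) and are verified by a
CDF round-trip guard (|pbeta(q) − p| ≤ 1e−8, else an error — never a
silent wrong interval). The log evidence is computed as
log B(α + k, β + n − k) − log B(α, β) entirely in log space, so it cannot
overflow for any counts. Degenerate frequentist inputs (k = 0 or k = n)
return the estimate with a flagged zero-width interval and a warning
rather than failing. Autocorrelations use the standard biased (1/N)
normalization with ρ₀ pinned to 1.

## Problem sizes

The package's own validation uses: full-length sampler runs (4 × 20,000
iterations, about a second) for oracle-equivalence checks; 50,000-person
generator runs for apparent-prevalence calibration (three binomial
standard errors); 1,000 closed-form replicates at n = 549 for
credible-interval coverage (the 95% interval covers a true prevalence of
0.59 in 93–97% of replicates); and randomized property tests (about 60
encounter sets against a brute-force pair-enumeration oracle, 8 random
generator configurations for the round trip). These sizes keep each check
sharp enough to detect one-digit errors in the formulas while running the
whole suite in well under a minute.

## Known limitations

* Single-parameter model only: no covariates, no multi-level structure.
* No misclassification adjustment in the likelihood (see above).
* The sampler is random-walk Metropolis; it is validated for this
  one-dimensional conjugate target and is not intended as a
  general-purpose MCMC engine.
* ESS values are sampler-specific: two correct samplers with different
  autocorrelation will report different ESS at identical posteriors, so
  ESS should be compared against thresholds, not across samplers.
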