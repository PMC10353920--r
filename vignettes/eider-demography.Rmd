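---
title: "From vital-rate evidence to demographic importance: methods behind vitalsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From vital-rate evidence to demographic importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalsynth)
```

## The problem

Conservation planning for long-lived, intermittently breeding birds needs two
things that rarely come packaged together: synthesised estimates of every
vital rate in the life cycle, and a measure of how much each life-cycle
transition actually matters for population growth. vitalsynth implements the
full chain for the common eider (*Somateria mollissima*), a seaduck with
deferred recruitment (first breeding between ages 2 and 5) and intermittent
breeding (established breeders skip some years), and exposes every step as a
reusable, testable function.

The chain is: a literature *evidence database* of published vital-rate
estimates; *screening* (verification, precision, sex, independence);
*synthesis* per rate (simple mean or precision-weighted random-effects
meta-analysis); assembly of a six-stage *projection matrix* with a discrete,
reversible nonbreeder stage; *perturbation analysis* (growth rate lambda,
elasticities); and a *mismatch analysis* comparing how often each transition
group has been studied with how much it contributes to lambda.

## The evidence database and its screening

One row per published estimate, with the twelve rate codes of
`vital_rate_codes()`. Three screening axes matter:

* **Verification and precision.** Unverified estimates (located only through
  a citation) and range midpoints are retained by default; their influence is
  checked by `sensitivity_compare()`, which re-runs the synthesis without
  them and asks whether the two means fall within each other's
  `1.96 * sqrt(variance)` intervals. The 1.96 interval is a package choice: a
  symmetric normal approximation is the weakest assumption available at this
  level of aggregation.
* **Sex.** The projection model is female-only (females are the limiting sex
  in ducks), so survival estimates that are male-only or sex-aggregated are
  dropped by the default policy. "Survival" here means `s1h`, `s1f`, `s2`,
  `sa`; the set is an argument of `screen_records()`.
* **Independence.** Estimates sharing underlying data are tied by an
  `independence_group`. Replicates within one study are collapsed by a
  *sub-meta-analysis* (same protocol as the main synthesis, applied within
  the study); groups spanning studies need an explicit rule
  (`"most_precise"`, `"keep:<study>"`, or a forced collapse), mirroring the
  case-by-case decisions such databases carry in their metadata.

## Synthesis: simple means and mean-adjusted precision weighting

Rates with a thin evidence base get a simple mean: the rule is conjunctive —
fewer than 20 independent estimates *and* more than a third of them lacking
sample sizes. Both thresholds are arguments of `choose_method()`. The
conjunctive reading is deliberate: a small set of fully sample-sized
estimates can still be precision-weighted, and only the combination of few
estimates and missing replication information leaves nothing for the
weighting scheme to work with.

For meta-analysed rates, study-level means \(\delta_i\) are combined with
mean-adjusted precision weights. With \(s^2\) the mean of the reported
study-level variances \(s_i^2\):

\[
v_i = s^2 / n_i, \qquad
T^2 = \max\!\left(0,\ \operatorname{var}(\delta_i) - \overline{v_i}\right),
\qquad W_i = \frac{1}{v_i + T^2},
\]

\[
\hat\theta = \frac{\sum W_i \delta_i}{\sum W_i}, \qquad
\operatorname{var}(\hat\theta) = \frac{1}{\sum W_i}.
\]

Two properties drive the design. First, replacing each study's own variance
by the pooled \(s^2/n_i\) removes the small-sample bias of self-reported
variances *and* lets studies that report a sample size but no variance be
weighted at all — exactly the situation of much of the wildlife literature.
Second, \(T^2\) is the Cochran/Hedges variance-component estimator; it can
go negative in finite samples and is truncated at zero, since a negative
between-study variance is meaningless and would break the weights.
\(\operatorname{var}(\delta_i)\) uses the sample (k−1) divisor. Estimates
without sample sizes are excluded from the meta path rather than imputed.

A subtlety worth stating: the scheme is only internally consistent if
\(s_i^2\) is the *population-level* sample variance of study *i* (so that
\(s^2/n_i\) estimates the error variance of its mean). The synthetic
generator follows that convention, drawing reported variances as
\(\sigma^2\,\chi^2_{n_i-1}/(n_i-1)\).

The estimator is checked three ways in the test suite: a two-study hand
oracle computed from the formulas above; agreement with an independent
Hedges-type implementation (`metafor::rma(method = "HE")`) on random inputs;
and Monte-Carlo calibration — across 1000 replicate synthetic databases of
k = 30 studies the meta-mean is unbiased to within 0.005 and the nominal 95%
interval covers the truth between 92% and 98% of the time. Those problem
sizes are the package's calibration conditions, chosen to match a realistic
adult-survival evidence base.

## The life cycle and projection matrix

The model is a birth-pulse, prebreeding-census, female-only matrix over six
stages: `1yo`, `PB2`–`PB4` (prebreeders aged 2–4), `B` (breeder), `NB`
(nonbreeder). Surviving 1-year-olds recruit with conditional propensity
`BP2` or defer; prebreeders recruit with `BP3`, `BP4`, and all survivors
recruit by age 5 (`BP5 = 1`). The `BPx` are *conditional* probabilities of
first breeding at age x given not yet recruited, which is what the matrix
elements need. The 1-year-old column is survived with `s2` (that transition
spans the second year of life); all older columns use adult survival `sa`,
because `s2` is defined only for the second year and no disaggregated
prebreeder survival exists.

Intermittent breeding is modelled structurally, not as a fertility discount:
surviving adults move breeder-to-breeder or nonbreeder-to-breeder with the
breeding propensity of established breeders (`BPeb = 0.72` in the eider
parameterisation) and to the nonbreeder state with its complement (0.28),
with the same `sa` underlying all four transitions. Setting `BPeb = 1`
collapses the model to a standard breeder-only life cycle with the
nonbreeder stage unreachable — a degenerate case the tests exercise.

Fertility is `F = 0.5 * CS * HS * s1 [* BPeb]`, with the 0.5 for an equal
hatching sex ratio, and `s1` selectable:

* `direct`: the survival-from-hatching estimate `s1h`;
* `fledging_product`: `FS * s1f`;
* `pooled` (default): the unweighted mean of the two pathways.

### Which fertility pathway? A resolved ambiguity

The two first-year-survival pathways disagree substantially for the eider
(0.37 direct vs 0.165 via fledging), so the fertility element ranges from
0.205 to 0.460 across plain modes — enough to move lambda from 0.98 to 1.08.
Reported asymptotic results for this parameterisation (lambda = 0.99;
continued-breeding elasticity 38%; breeding/nonbreeding switching 24%;
fertility 11%) are reproduced by *none* of the three plain pathways, but are
reproduced simultaneously and exactly (after rounding) by the pooled pathway
with fertility additionally conditioned on `BPeb`
(`F = 0.5 * 4.08 * 0.61 * 0.2675 * 0.72 = 0.240`):

```{r sweep}
sweep_fertility_modes(eider_vital_rates())
```

The package therefore defaults to `mode = "pooled"` with
`propensity_adjust = TRUE`. Biologically, the adjustment reads the breeder
stage as established breeders of whom only a fraction `BPeb` attempt in a
given year. Under a strict prebreeding census that fraction is already
carried by the state transitions, so users who regard the adjustment as
double-counting intermittent breeding can set `propensity_adjust = FALSE`;
`sweep_fertility_modes()` makes the consequences of every choice explicit.

## Perturbation analysis

`elasticity_matrix()` computes the dominant eigenpair with R's dense solver
(`eigen()`), selecting the largest-modulus real nonnegative eigenvalue, and
forms sensitivities \(s_{ij} = v_i w_j\) (with \(\langle v, w\rangle = 1\))
and elasticities \(e_{ij} = (a_{ij}/\lambda)\, v_i w_j\). Numerical
contracts, all tested: elasticities are nonnegative, zero on structural
zeros, sum to 1 within 1e-10, and per-stage row sums equal column sums
within 1e-10; the eigenvector formula agrees with a finite-difference
derivative oracle (`a_ij -> a_ij (1 + 1e-6)`) to 1e-4 relative error on
random matrices. Reducible matrices (e.g. `BPeb = 1`) are handled on the
full matrix, with unreachable stages legitimately carrying zero stable
mass. Reported percentages round half away from zero.

For comparison with study effort, elasticities are grouped
(`eider_grouping()`): *Reproduction* (the fertility element), *Breeding
transitions* (the four breeder/nonbreeder elements) and *Recruitment*
(everything left of the breeder column). The headline summary
(`eider_elasticity_summary()`) separates continued breeding, the two
state-switching elements, and continued nonbreeding. The reported "24%"
switching figure is the two-element sum B→NB + NB→B; continued nonbreeding
(≈4% here, below the display threshold of a typical elasticity figure) is
tracked separately. These two elasticities are always equal for this
life-cycle structure — a consequence of the NB column and row being
proportional to the B column's nonbreeding route — and the tests assert it
across jittered parameterisations.

## Study effort, mismatch, and the null

Fractional study effort per group is the number of distinct studies touching
any rate mapped to that group, divided by total distinct studies (129 in the
eider database: 39 Recruitment, 38 Breeding transitions, 103 Reproduction).
Because studies span groups, fractions need not sum to 1 and are not
renormalised.

The chance-probability rule treats observed effort against importance under
a Uniform(0, 1) null for effort, one-sided on the observed side of the 1:1
line: over-representation at least as extreme has probability `1 - effort`,
under-representation has probability `effort`, zero deviation has
probability 1. This is the unique null consistent with both worked
representation examples (elasticity 0.3 with effort 0.6 gives 0.4; 0.6 with
0.3 gives 0.3), and `contour_grid()` tabulates it over the unit square. The
companion `simplex_null_simulation()` reproduces the qualitative argument
for why mismatches are expected by chance: uniform draws of k fractions
summing to 1 typically contain one large and several small fractions
(closed-form checks: P(max ≥ 0.75) = 0.5 at k = 2; P(max ≥ 0.5) = 0.75 at
k = 3). Which of the two generative stories produced any particular
published contour figure is not asserted; the closed form is primary and the
simulation is provided alongside it.

## The synthetic generator: what it does and does not emulate

`generate_database()` draws study means from the same random-effects
structure the estimator targets, \(\delta_i \sim N(\theta, T^2_{true} +
\sigma^2/n_i)\), truncated to the rate's legal domain, with configurable
missingness of sample sizes and variances, within-study multi-year
replicates, and verification/midpoint flags.
`eider_synthetic_config()` sets the defaults to the structure of the eider
evidence base: ground-truth means at the published species-wide values,
study counts per rate as reported there (3/3/7/35/7/7/91/27/13 for
s1h/s1f/s2/sa/FB/BPeb/CS/HS/FS), sparse rates mostly lacking sample sizes —
which is precisely what routes them to the simple-mean path — and the
heavily studied rates carrying replicates and partial metadata.
Between-study standard deviations were chosen once, at values a field
demographer would call realistic for each rate (e.g. 0.03 for adult survival
of a long-lived seaduck, 0.3 eggs for clutch size); they are not fitted to
anything.

Design choices worth knowing:

* **Truncated normal, not logit-normal**, for probability rates: the
  estimator operates on the raw scale, and at the parameter values used the
  truncation bias is negligible (the degenerate and calibration tests
  monitor it). The generator resamples on domain violation up to a bounded
  retry count, then warns and clamps.
* **Counter-based substreams**: each (rate, study) pair seeds its own RNG
  substream derived from the configuration seed, so enlarging a
  configuration never perturbs earlier studies' draws.
* **Not emulated**: spatial covariance among colonies, temporal covariation
  of rates, subspecies structure beyond a pass-through column, and
  study-level overlap of rates within one study (synthetic studies estimate
  one rate each). Passing tests on synthetic data therefore demonstrate
  estimator and pipeline correctness under the stated generative model, not
  robustness to those real-data features.

## Problem sizes and tolerances used by the test suite

Chosen as the package's own testing conditions: 1000 replicate databases of
30 studies for estimator calibration; 12–20 random matrices per perturbation
property; 10^4 simplex draws against closed forms (three Monte-Carlo
standard errors) and 10^5 for convergence to the analytic deviation null
(tolerance 0.01); eigen tolerances 1e-10 for identities and 1e-4 relative
against the finite-difference oracle.

## Known limitations

* The mean model is a species-wide average; it is not a parameterisation of
  any one colony, and lambda = 0.99 inherits every caveat of averaging
  vital rates across a large geographic range.
* The fertility-pathway default is a reconstruction justified by agreement
  with reported results, not by an explicit statement in any source; both
  alternatives remain first-class options.
* The uniform-effort null penalises any deviation from 1:1
  proportionality; in practice only gross over/under-study is actionable,
  and the probabilities should be read as descriptive, not inferential.
* No stochastic, transient, or retrospective (LTRE) analyses: the scope is
  asymptotic prospective perturbation plus study-effort comparison.
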