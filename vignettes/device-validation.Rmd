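---
title: "Validating blood-pressure devices under ISO 81060-2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating blood-pressure devices under ISO 81060-2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpvalidate)
```

## The problem

A non-invasive blood-pressure (BP) device — a cuff monitor, or increasingly
a cuffless estimator such as a smartphone photoplethysmography app — is
considered clinically acceptable when it agrees with a rigorously derived
auscultatory reference under the ISO 81060-2:2018 standard and the
AAMI/ESH/ISO consensus protocol. The protocol is demanding in ways that go
well beyond a mean and a standard deviation: the reference must come from
two blinded observers reading the same cuff simultaneously, rounds are
discarded under precise agreement rules, subjects are excluded in a fixed
cascade order, the analytical sample must cover prescribed BP and sex
distributions, and two distinct accuracy criteria must hold.

`bpvalidate` implements that evaluation pipeline as reusable, tested
components, together with a synthetic-study simulator so the whole chain
can be exercised and property-tested without access to field data.

## Reference derivation and the exclusion cascade

Each measurement round consists of two simultaneous nurse readings and one
device reading. The round contributes a *valid paired measurement* when
the device produced a value and the nurses agree within 4 mmHg on both
arms; the reference is then the per-arm mean of the two nurse readings
(`validate_round()`).

`run_cascade()` applies the protocol's exclusions in their fixed order:

1. device failure (signal not captured, poor quality, irregular heart
   rate, outlier, missing), measurement level;
2. inter-nurse disagreement > 4 mmHg, measurement level;
3. subjects left with fewer than three valid pairs, subject level;
4. subjects with excessive within-subject reference variability,
   subject level.

Each record carries exactly the first reason that removed it, so the
ledger tallies are conserved: retained plus excluded equals input at both
the measurement and the subject level. Rounds failing both the device and
the inter-nurse rule are counted under stage 1 and reported separately as
overlap, since in cold-weather field conditions the two failure modes can
coincide heavily.

The protocol's wording for stage 4 ("systolic BP differed by > 12 mmHg or
> 8 mmHg in diastolic across 2 out of the 4 rounds") leaves the comparison
point unstated. We read it as: a subject is excluded when at least two
rounds have a reference value deviating from the subject's median
reference by more than 12 mmHg (SBP) or 8 mmHg (DBP). The rule lives in a
single internal predicate (`reference_variability_flag`) so an alternative
reading (e.g. pairwise round differences) can be swapped in without
touching the cascade. The median was chosen over the mean as the
comparison point because the rule is itself an outlier screen.

Two further interpretation choices: the 4-mmHg validity rule is applied
jointly to SBP and DBP — a round is one paired reading, and both arms'
analyses must use the same measurement set — and the "fewer than three
pairs" count is evaluated after stages 1–2, consistent with the stated
order.

## Criterion 1 and criterion 2

With $e_i = \text{device}_i - \text{reference}_i$ pooled over all retained
measurements, **criterion 1** requires

$$-5 \le \bar e \le 5 \quad\text{and}\quad s_e \le 8 \text{ mmHg},$$

with $s_e$ the sample SD ($n-1$ denominator, used throughout — it also
keeps the degenerate two-subject criterion-2 case well defined). The
comparisons are inclusive and made on unrounded statistics.

**Criterion 2** averages each subject's errors and bounds the
between-subject SD of those means by a ceiling that depends on the pooled
mean error: the unique $s$ at which a normal error distribution
$X \sim N(|\bar e|, s^2)$ satisfies

$$P(|X| \le 10\,\text{mmHg}) = 0.85.$$

The defining constants (10 mmHg tolerable error, 85% coverage) come from
the standard; `max_permissible_sd()` exposes them as arguments and solves
the coverage equation by bracketed root-finding (`stats::uniroot`,
tolerance 1e-10, bracket $(10^{-8}, 10^3)$ — coverage is strictly
decreasing in $s$, so the root is unique). The solution is symmetric in
the sign of the mean error and strictly decreasing in its magnitude; the
ceiling is undefined for $|\bar e| \ge 10$, where the function refuses to
answer rather than extrapolate.

The standard also publishes the ceiling as a lookup table at 0.1-mmHg
resolution, which we embed as `iso_criterion2_table`. Recomputation
reproduces 48 of its 51 cells to ±0.01 mmHg; three cells (mean errors 3.6,
4.8 and 5.0) differ by 0.02, with inconsistent signs, which no smooth
monotone ceiling function can reconcile — we treat those entries as
transcription noise in the published table. Because published study
reports quote thresholds *from the table*, `table_mode = TRUE` first
rounds the mean error to the nearest 0.1 and reads the embedded table,
reproducing quoted thresholds exactly; the default mode computes the root.
`criterion2_check()` applies either mode to summary statistics when only a
published mean error and observed SD are available.

## Sampling audits and screening

`audit_sampling()` checks the analytical sample against the consensus
composition rules. For general populations the band fractions are
computed over the *reference values of retained measurements* (the
convention under which study reports tabulate their BP distributions):
at least 5% of systolic values ≤ 100, 5% ≥ 160, 20% ≥ 140 mmHg; 5% of
diastolic ≤ 60, 5% ≥ 100, 20% ≥ 85 mmHg; at least 85 subjects and 30% of
each sex. Note the diastolic "61–85" descriptive band overlaps the
"≥ 85" requirement; the requirement text wins and ≥ 85 is evaluated
inclusively. For pregnant cohorts the audit classifies subjects at
enrollment (`classify_pregnant()`: normotensive < 140/90; otherwise
pre-eclampsia when proteinuria is present, else hypertensive) and
requires at least 20 subjects per group and 45 overall.

`screen_subject()` applies the enrollment rules in order — age range
(18–80 general, 18–50 pregnant), between-arm difference (> 15 systolic or
> 10 diastolic excludes), resting-BP ceiling (> 180/120 general,
> 160/110 pregnant) — reporting the first failed rule, as an enrollment
flow diagram would.

## Agreement statistics

`bland_altman()` computes the conventional per-pair means and
differences, the bias, and limits of agreement at bias ± 1.96 SD. The
bias is definitionally the criterion-1 mean error on the same pairs, and
the package asserts that equality across modules in its tests. Repeated
measurements per subject are pooled without a repeated-measures
correction — matching how multi-site validation reports draw their plots —
with `per_subject = TRUE` available to aggregate first; the lack of a
correlation correction in the pooled version is a known limitation of
that presentation, not of the data.

`qualify_observers()` implements the pre-study inter-rater requirement:
on exactly 50 practice measurements, both SBP and DBP differences within
5 mmHg on ≥ 45 and within 10 mmHg on ≥ 48, tolerances inclusive.

## The synthetic-study generator

The simulator exists so that every stage above is testable, including the
statistical behaviour of the criteria. Its error decomposition is the
simplest structure that makes both ISO criteria *and* the inter-nurse
rule simultaneously meaningful:

* subject truth $(S_j, D_j)$ drawn from a mixture of correlated bivariate
  normals, quantized to the cuff gradation;
* per round, a latent auscultatory signal = truth +
  $N(0, \sigma_\text{round}^2)$ shared by both nurses and the device
  (default 2 mmHg of genuine round-to-round BP fluctuation);
* each nurse reads the signal plus independent
  $N(0, \sigma_\text{obs}^2 + \sigma_\text{extra}^2)$ error, quantized to
  the 2-mmHg sphygmomanometer gradation (configurable). Defaults
  $\sigma_\text{obs} = 1.5$, $\sigma_\text{extra} = 0.8$ make roughly 18%
  of rounds fail the 4-mmHg agreement rule, the order observed in
  multi-site field work;
* the device, when it returns a value, reports
  $w \cdot \text{calibration} + (1-w) \cdot \text{signal} + b_j +
  N(0, \sigma_\text{within}^2)$ with subject bias
  $b_j \sim N(\beta, \sigma_\text{between}^2)$. The anchor term models
  the one-time cuff calibration that cuffless estimators require
  ($w = 0.5$ by default); the calibration value is the nurses' cuff
  average from a dedicated calibration round with up to six device
  attempts, and a subject whose calibration never succeeds produces no
  device readings at all;
* device failures occur independently per round with probability
  $p \times \text{cold multiplier}$ and draw a status from the failure
  mixture, whose default is the pooled field distribution of failure
  reasons (signal not captured 63.8%, poor quality 19.0%, irregular heart
  rate 10.3%, outlier 2.1%, missing 4.1% — renormalized, as the printed
  shares total 99.3%);
* sessions follow the protocol workflow: rounds repeat until four valid
  paired readings or eight attempts.

Under this model the per-measurement error variance is
$\sigma_\text{between}^2 + w^2(\sigma_\text{round}^2 + q) +
[w^2\sigma_\text{round}^2 + \sigma_\text{within}^2 + q]$ and the
between-subject variance of $k$-round means replaces the bracket by
bracket$/k$, where $q$ is the reference-noise variance (half the per-nurse
variance plus a $g^2/24$ quantization term). `scenario()` inverts this
decomposition in closed form to build configurations whose simulated
criterion statistics land, in expectation, on chosen targets; the four
shipped scenarios target the published statistics of a pregnant hospital
cohort and two general community cohorts (plus a cold-weather variant with
a 2.5× failure multiplier), with BP mixtures that satisfy the sampling
bands except for the deliberately recreated upper-systolic recruitment
shortfall of the `BN` scenarios.

What the generator does *not* emulate: PPG waveforms and their
physiology, non-normal or skewed observer error, digit preference beyond
gradation rounding, within-session BP drift, failure-mode dependence
across rounds (none is documented), and site-specific failure mixtures
(only a pooled default is known). Passing pipeline tests on simulated
data therefore demonstrates correctness of the *evaluation machinery*
and the statistical calibration of the criteria under a plausible error
model — not device performance on real populations.

## Numerical choices and degenerate inputs

* Root finding: `uniroot` to 1e-10 on a fixed bracket; the returned
  ceiling always satisfies the coverage equation to < 1e-6, which the
  test suite verifies directly.
* Rounding: verdicts always compare unrounded statistics; printed output
  rounds means/SDs to 1 decimal and thresholds to 2, the reporting
  convention. `table_mode` is the only place rounding affects a verdict,
  by design.
* Degenerate inputs: criteria refuse samples of fewer than two values,
  criterion 2 refuses subjects with fewer than three pairs (a cascade
  violation) or fewer than two subjects; an all-failure study evaluates
  to an explicit `not_evaluable` report rather than an error; an
  all-zero error vector gives SD 0 and passes.
* Reproducibility: `generate_study()` seeds from its config, restores
  the caller's RNG state, and is bit-identical per seed.

## Problem sizes

The shipped tests run the full pipeline on simulated cohorts of 5–153
subjects; statistical properties use 200 replicates at 100 subjects for
parameter recovery (criterion-1 mean within ±0.2 mmHg of the configured
bias; criterion-2 SD within ±0.3 of the variance-decomposition
prediction), 1,000 randomized small studies for cascade conservation and
idempotence, and 10,000 simulated pairs for limits-of-agreement coverage.
These sizes give Monte-Carlo error comfortably inside the asserted
tolerances while keeping the suite quick on a laptop.
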