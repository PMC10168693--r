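---
title: "Methods: contrasting multilaboratory and single-laboratory effect estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting multilaboratory and single-laboratory effect estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multilabmeta)
```

## The problem

Preclinical multilaboratory studies run one protocol at two or more
independent sites. Meta-epidemiological work in clinical trials has long
shown that single-center trials tend to report larger treatment effects and
weaker methodology than multicenter trials; this package implements the
machinery to ask the same question of animal studies: given one
multilaboratory study and a matched set of up to ten single-laboratory
studies of the same intervention, disease model, and outcome, how do the
effect estimates and the methodological rigor compare?

Every stage consumes arm-level summary statistics (mean, SD or SE, n per
arm) as they would be extracted from published reports, so the package works
from extraction sheets, not raw data.

## Effect sizes

Outcomes differ in units across studies (infarct volume, locomotor counts,
glucose), so all effects are standardized mean differences. For a
treatment/control pair of arms,

$$d = \frac{\bar x_t - \bar x_c}{s_\text{pool}}, \qquad
s_\text{pool}^2 = \frac{(n_t-1)s_t^2 + (n_c-1)s_c^2}{n_t+n_c-2},$$

with large-sample variance
$\mathrm{var}(d) = \frac{n_t+n_c}{n_t n_c} + \frac{d^2}{2(n_t+n_c)}$.
The default metric is Hedges' *g*: $g = J\,d$ and
$\mathrm{var}(g) = J^2\,\mathrm{var}(d)$ with
$J = 1 - 3/(4(n_t+n_c-2) - 1)$. *g* is the default because the single-lab
studies in this domain are small (median total n around 19), where *d*'s
upward small-sample bias is material; Cohen's *d* remains available via
`metric = "d"`. SEs are converted to SDs as $SE\sqrt{n}$, the only
conversion possible from extracted summaries.

Outcomes have opposite polarities (lower infarct volume is good, higher
cognitive score is good), so each effect is oriented onto a
benefit-positive scale before any pooling: `orient()` flips the sign for
`lower_is_better` outcomes. Orientation is an involution and preserves the
variance.

All confidence intervals are plain normal intervals, point ± 1.96·se. No
Knapp–Hartung adjustment is applied: the package mirrors the conventional
inverse-variance practice of the commercial meta-analysis software used for
this kind of extraction-based synthesis, and mixing interval types between
stages would make the per-comparison and pooled intervals incomparable.

## Pooling

Within a comparison, the single-lab effects are pooled with a
DerSimonian–Laird random-effects model: Cochran's
$Q = \sum w_i (x_i - \bar x_{FE})^2$,
$\hat\tau^2 = \max\!\big(0, (Q - (k-1))/C\big)$ with
$C = \sum w_i - \sum w_i^2 / \sum w_i$, and re-weighting by
$w_i^* = 1/(v_i + \hat\tau^2)$. DL is the estimator the field's standard
tools default to for this workflow; REML would be a reasonable alternative
but would change nothing structurally, and DL keeps every pooled quantity
closed-form and brute-force checkable (the test suite re-derives every pool
with naive loop arithmetic to 1e-12 and cross-checks against
`metafor::rma(method = "DL")`).

A comparison has exactly one multilaboratory study, so "pooling" the
multilab side with $k=1$ returns that estimate with $\tau^2 = 0$. A
multilab study reported as per-center strata is first reduced to one
estimate by random-effects pooling of the per-center SMDs; a study reported
as aggregate arms is used directly. Published reports do not always say
which form the analysis used, so both are supported and the simulator can
generate either (`aggregate_multilab`).

## The design contrasts

For comparison $i$ with pooled single-lab effect $d_{s,i}$ and multilab
effect $d_{m,i}$ (both benefit-positive):

* **DSMD**: $\mathrm{DSMD}_i = d_{s,i} - d_{m,i}$, with
  $se_i^2 = se_{s,i}^2 + se_{m,i}^2$ treating the two designs as
  independent (they share no animals or labs). Positive values mean larger
  effects in single-lab studies.
* **ESR**: $\mathrm{ESR}_i = d_{s,i} / d_{m,i}$; 1 means no difference.
  The ESR is reported as a plain ratio. Ratios are unstable near a zero
  denominator, so comparisons with $|d_{m,i}|$ below a tolerance (default
  1e-8 on the SMD scale) are flagged degenerate and excluded from the
  median with a warning. Even above the tolerance a small multilab effect
  can produce extreme ratios, which is why the corpus summary is the median
  and range, never a mean.

Corpus-level summaries: the pooled DSMD (random-effects inverse-variance
pool of the per-comparison DSMDs, with an equal-weights variant behind
`pool_weights = "equal"` since published analyses do not always state the
weighting), the median ESR over non-degenerate comparisons, the count of
comparisons with strictly positive DSMD (exact zeros reported separately as
ties), and the count of comparisons whose multilab 95% CI and pooled
single-lab 95% CI are disjoint intervals. "Disjoint" is the one reading of
"CI falls outside" that is well defined when one interval nests inside the
other; nested intervals intersect and therefore do not count.

## Quality comparison

Five binary bias-reducing practices are scored per study: randomization,
low-risk randomization method, blinding of personnel, blinding of the
outcome assessor, and complete outcome data. The 0–5 totals are compared
between designs with a Mann–Whitney U test: U from midranks, the exact rank
distribution when $n_1 n_2 \le 400$ with no ties, and the tie-corrected
normal approximation with continuity correction otherwise (quality scores
are heavily tied at realistic corpus sizes, so the approximate path is the
one that matters in practice; the exact path matters for small tests and is
verified against full permutation enumeration). Per-practice adherence
percentages are reported descriptively only — no per-item tests, since five
correlated binary items at these sample sizes would invite spurious
precision.

## Matching single-lab studies

When more than ten candidate single-lab studies are eligible, selection
uses a transparent weighted-sum similarity to the multilab study: binary
matches for species and sex, and $1/(1+|\Delta|)$ proximities for
intervention timing, dose, measurement time, and publication year, each
weighted (defaults all 1) with missing features contributing 0. Published
selection practice describes the criteria but not a scoring function, so
the functional form here is a package design choice made for auditability:
every selection logs per-feature contributions, and ties at the k-th
position are broken by a seeded uniform draw recorded in the output —
reproducible, unlike ad-hoc random selection.

A hierarchical reading of the criteria (species first, then timing, ...) is
representable by making the weights strongly graded, so the weighted sum
subsumes both interpretations.

## The synthetic-data generator

`sim_config()` / `simulate_corpus()` generate matched corpora with known
ground truth. Everything is on the standardized scale (unit within-group
SD): the analysis consumes SMDs, so native units would add nothing. Per
comparison $i$: a true effect $\delta_i \sim N(\mu_\delta,
\tau_\text{comparison}^2)$; a multilab study with $C$ centers, per-center
shifts $\sim N(0, \tau_\text{center}^2)$, and per-arm normal samples
summarized per center; and $S$ single-lab studies with effects
$\delta_i + \text{bias}_\text{single} + u_j$, $u_j \sim N(0,
\tau_\text{single}^2)$, at small n. Optional significance-gated selection
redraws a single-lab study until its two-sided Welch t-test has p < 0.05
(up to `max_redraws`, default 20, keeping the last draw with a warning when
the gate cannot be met) — a minimal model of publication bias. Quality
flags are Bernoulli draws at per-design rates.

Defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_comparisons` | 14 | size of the published matched corpus |
| `mu_delta` | 0.5 | a moderate preclinical treatment effect |
| `tau_comparison` | 0.3 | diseases from stroke to diabetes differ substantially |
| `n_centers` | 2–5 | observed range of experimental centers |
| `n_per_arm_multi` | 8–24 | gives median multilab totals near the observed 111 |
| `n_singles` | 4–10 | up to the 10-study cap used in matching |
| `n_per_arm_single` | 5–14 | gives median single-lab totals near the observed 19 |
| `bias_single` | 0 | null baseline; experiments inject inflation explicitly |
| `tau_single` | 0.3 | moderate between-lab heterogeneity |
| `tau_center` | 0.2 | centers under one protocol vary less than independent labs |
| `quality_probs` | multilab {.94,.19,.69,.75,.38}; single {.57,.07,.24,.53,.38} | observed per-design practice rates |

One master seed draws per-comparison substream seeds, so corpora are
bit-identical across reruns and any single comparison can be regenerated
alone.

What the generator does *not* emulate: non-normal or skewed outcomes,
unequal arm sizes, multiple outcomes per study, correlation between quality
and effect size, heterogeneous variances between arms, and species/sex
structure beyond bookkeeping columns. Passing recovery tests therefore
shows the estimators do what they claim under the stated generative model —
not that real extraction sheets satisfy that model.

## Numerical choices and degenerate inputs

* Medians use the midpoint convention for even counts.
* "NR" (not reported) sample sizes are excluded from medians, ranges, and
  totals; a study running several species contributes one sample-size entry
  per species cohort; a center that is both experimental and coordinating
  is counted once in the total. These three conventions are what make the
  descriptive summaries match the published corpus table.
* Zero pooled SD with unequal means is an error (the SMD is undefined);
  with equal means it returns a flagged zero-effect estimate with `NA`
  variance so it cannot silently enter a pool.
* `dl_tau2` with one study returns 0 with a message rather than erroring,
  because a lone multilab estimate legitimately flows through the same
  pooling path.
* Direction counts use strict inequality; exact zeros are reported as ties.

## Known limitations

**Small-study weighting bias.** The LS variance of an SMD contains
$d^2/(2N)$, so a study that randomly overshoots gets a larger variance and
a smaller inverse-variance weight. Pooling many small studies with large
true effects therefore pulls the pooled estimate slightly toward zero; the
effect grows with the true effect and shrinks with n. In the recovery
experiment (`analysis/05_recovery.R`, and the corresponding acceptance
check) this appears as a recovered pooled DSMD a few percent below an
injected inflation of 0.7 when the single-lab studies' true effects are
around 1.2 at 5–14 animals per arm — per-study Hedges' g is unbiased there
(the unweighted mean recovers the truth), so the shortfall is attributable
to the weighting, which is shared with standard inverse-variance practice
rather than specific to this implementation. Users comparing designs should
read small pooled-DSMD differences with this in mind; the equal-weights
pooling mode removes the across-comparison layer of this bias at the cost
of efficiency.

**Coverage.** With ~14 comparisons, DL + z intervals are known to be
slightly liberal when between-comparison heterogeneity must be estimated;
the zero-bias coverage experiment quantifies this under the generator's
conditions rather than assuming nominal behavior.

**Ratio instability.** The ESR is undefined in the limit of a null multilab
effect and volatile near it; the degenerate flag and median/range reporting
mitigate but do not remove this. The DSMD is the better-behaved contrast
and is the one that gets pooled.

## Problem sizes used by the tests and scripts

The test suite and `scripts/acceptance.R` use 1,000 random instances for
the pooling-oracle equivalence, full permutation enumeration up to
$n_1+n_2=10$ for the U test, a 200-comparison corpus for recovery of an
injected 0.7 inflation, 200 replicates of 14-comparison corpora for
zero-bias coverage, and a 400-comparison corpus (~2,000 studies) for the
quality-flag law-of-large-numbers check. These sizes were chosen so every
Monte-Carlo check has its error bounded by explicit binomial or pooled-se
arithmetic while the whole suite stays desk-scale.
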