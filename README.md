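# multilabmeta

Meta-epidemiological comparison of preclinical **multilaboratory** studies
(one protocol, two or more independent sites) with matched
**single-laboratory** studies of the same intervention, disease model, and
outcome. Clinical meta-epidemiology has repeatedly found that single-center
trials report larger treatment effects and weaker methodology than
multicenter trials; this package provides the statistical machinery to run
that comparison in the preclinical domain, starting from nothing more than
the arm-level summary statistics (mean, SD or SE, n) that can be extracted
from published reports.

It is written for meta-researchers and systematic reviewers of animal
studies: people who assemble extraction sheets of matched study sets and
need the effect-size, pooling, and contrast layers to be reproducible and
auditable.

## The statistics

For each two-arm study, a standardized mean difference

d = (x̄_t − x̄_c) / s_pool,  var(d) = (n_t+n_c)/(n_t·n_c) + d²/(2(n_t+n_c)),

by default small-sample corrected to Hedges' g = J·d with
J = 1 − 3/(4(n_t+n_c−2) − 1). Effects are oriented so positive always means
benefit. Within each comparison, the single-lab studies are pooled with a
DerSimonian–Laird random-effects inverse-variance model. The design
contrasts are then, per comparison *i*:

- **DSMD_i = d(single-lab pool)_i − d(multilab)_i** — positive values mean
  larger effects in single-lab studies; pooled across comparisons by
  random-effects inverse variance with se² = se²_single + se²_multi.
- **ESR_i = ES(single-lab pool)_i / ES(multilab)_i** — 1 means no
  difference; summarized as median (range).

Alongside: descriptive synthesis of study characteristics (sample sizes,
species, centers), a 0–5 methodological-quality score over five
bias-reducing practices compared between designs with a Mann–Whitney U
test, similarity-based matching of candidate single-lab studies to a
reference multilab study, and a synthetic-data generator with known ground
truth for recovery and coverage experiments. The methods vignette
(`vignettes/design-contrast-methods.Rmd`) documents every model, default,
and known limitation.

## Worked example

```r
library(multilabmeta)

# descriptives of the bundled multilaboratory corpus table
ch <- read_characteristics(multilab_characteristics_path())
summarize_characteristics(ch)
#> Sample size: median 111 (range 23-384), total 2145 animals; 91% lab rodents

# a synthetic matched corpus with a known single-lab inflation of 0.72
corpus <- simulate_corpus(sim_config(bias_single = 0.72, seed = 101))
res <- run_pipeline(corpus$studies)
print(res$contrast)
#> Design contrast over 14 comparisons (metric: g)
#>   pooled DSMD: 0.70 [95% CI 0.54, 0.86], z p = 6.35e-17
#>   median ESR: 1.90 (range -543.66-22.44)
#>   single-lab effect larger in 14/14; ESR > 1 in 11/14; disjoint CIs in 6/14
print(res$quality)
#> Quality scores: multilab median 3 (range 1-4, n = 14) vs single 2 (range 0-5, n = 89)
#>   Mann-Whitney U = 896, two-sided p = 0.00594
#>   scores >= 3: 71% multilab vs 22% single
```

The pooled DSMD of 0.70 [0.54, 0.86] recovers the injected inflation of
0.72: across these 14 simulated comparisons the single-lab studies
systematically overstate the treatment effect, and every comparison points
in that direction. The quality comparison shows the multilab studies
adhering to more bias-reducing practices (median 3 of 5 vs 2 of 5). The
extreme lower end of the ESR range illustrates why ratios are summarized by
the median: one comparison's multilab effect is near zero, making its ratio
unstable (the DSMD for the same comparison is well behaved).

To analyze real extraction sheets, put them in the documented CSV schema
(see `?read_studies`) and call `run_pipeline("your_studies.csv",
out_dir = "out/")`; the output directory gets the per-comparison table, the
effects table, JSON reports, forest plots, and a manifest with the seed and
config hash.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (descriptives → corpus simulation → design contrast → quality →
recovery experiments), writing their tables under `results/`.

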