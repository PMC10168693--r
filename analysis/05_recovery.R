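#!/usr/bin/env Rscript
# Parameter-recovery experiments for the pooled DSMD:
#   (a) a 200-comparison corpus with an injected single-lab inflation of 0.7,
#   (b) empirical 95% CI coverage under zero design bias (200 replicates of a
#       14-comparison corpus),
#   (c) the directional effect of significance-gated selection at small n.
# Writes results/recovery.json.

library(multilabmeta)

message("(a) injected inflation 0.7, 200 comparisons")
cfg_bias <- sim_config(n_comparisons = 200, bias_single = 0.7, seed = 301)
rep_bias <- design_contrast(simulate_corpus(cfg_bias)$studies)
message(sprintf("    recovered pooled DSMD %.3f (se %.3f); note the small-study",
                rep_bias$pooled_dsmd$point, rep_bias$pooled_dsmd$se))
message("    inverse-variance weighting bias discussed in the methods vignette")

message("(b) zero-bias coverage, 200 replicates")
cov <- recovery_experiment(sim_config(bias_single = 0, seed = 302),
                           n_replicates = 200, seed = 302)
message(sprintf("    pooled-DSMD 95%% CI covered 0 in %.1f%% of replicates (bias %.4f, RMSE %.4f)",
                100 * cov$coverage, cov$bias, cov$rmse))

message("(c) significance-gated selection, zero bias, small single-lab arms")
cfg_sel <- sim_config(n_comparisons = 60, bias_single = 0, mu_delta = 0.3,
                      tau_comparison = 0, n_per_arm_single = c(5, 10),
                      selection = TRUE, seed = 303)
rep_sel <- design_contrast(suppressWarnings(simulate_corpus(cfg_sel))$studies)
cfg_nosel <- cfg_sel
cfg_nosel$selection <- FALSE
rep_nosel <- design_contrast(simulate_corpus(cfg_nosel)$studies)
message(sprintf("    pooled DSMD %.3f with the gate vs %.3f without",
                rep_sel$pooled_dsmd$point, rep_nosel$pooled_dsmd$point))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(
    injected_bias = list(target = 0.7, n_comparisons = 200,
                         pooled_dsmd = rep_bias$pooled_dsmd$point,
                         se = rep_bias$pooled_dsmd$se,
                         prop_single_larger = rep_bias$n_single_larger / 200),
    zero_bias_coverage = list(n_replicates = cov$n_replicates,
                              coverage = cov$coverage, bias = cov$bias,
                              rmse = cov$rmse),
    selection = list(pooled_dsmd_gated = rep_sel$pooled_dsmd$point,
                     pooled_dsmd_ungated = rep_nosel$pooled_dsmd$point)
  ),
  "results/recovery.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/recovery.json")
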