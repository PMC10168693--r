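#!/usr/bin/env Rscript
# Descriptive synthesis of the multilaboratory study corpus: sample sizes,
# species mix, and center counts. Writes results/characteristics.json.

library(multilabmeta)

ch <- read_characteristics(multilab_characteristics_path())
s <- summarize_characteristics(ch)
cen <- summarize_centers(ch)

print(s)
message(sprintf("centers per study: median %g total (range %g-%g), median %g experimental (range %g-%g)",
                cen$median_total, cen$range_total[1], cen$range_total[2],
                cen$median_experimental, cen$range_experimental[1], cen$range_experimental[2]))
message("species cohorts: ", paste(names(s$species_counts), s$species_counts,
                                   sep = "=", collapse = ", "))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(median_n = s$median_n, n_range = s$n_range,
       total_animals = s$total_animals, pct_rodent = s$pct_rodent,
       species_counts = as.list(s$species_counts),
       sex_counts_cohort = as.list(s$sex_counts_cohort),
       sex_counts_study = as.list(s$sex_counts_study),
       median_centers_total = cen$median_total, range_centers_total = cen$range_total,
       median_centers_experimental = cen$median_experimental,
       range_centers_experimental = cen$range_experimental),
  "results/characteristics.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/characteristics.json")
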