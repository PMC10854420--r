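#!/usr/bin/env Rscript
# Simulate a small synthetic plasma cohort: diploid controls plus samples
# carrying the recurrent uveal-melanoma karyotypes at a range of ctDNA
# tumor fractions. Counts are written as fixedStep WIG, the format the
# read-counting stage produces from real alignments.
#
# Depth is kept at 5 million fragments here so the cohort builds in
# seconds; the spike-in study (05) runs at the full 25 million.

library(plasmacnv)

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

grid <- build_bin_grid(grch37_genome(), 1e6)
arch <- uveal_archetypes()

cohort <- expand.grid(
  archetype = c("neutral", "monosomy3_8qgain", "fig4_metastatic"),
  tumor_fraction = c(0, 0.05, 0.25),
  stringsAsFactors = FALSE
)
cohort <- cohort[!(cohort$archetype == "neutral" & cohort$tumor_fraction > 0), ]
cohort$sample <- sprintf("%s_f%02d", cohort$archetype,
                         round(100 * cohort$tumor_fraction))
cohort$seed <- 100 + seq_len(nrow(cohort))

for (i in seq_len(nrow(cohort))) {
  cfg <- sim_config(grid, n_fragments = 5e6,
                    tumor_fraction = cohort$tumor_fraction[i],
                    profile = arch[[cohort$archetype[i]]],
                    seed = cohort$seed[i])
  bc <- simulate_bin_counts(cfg)
  write_wig(bc, file.path("results/cohort",
                          paste0(cohort$sample[i], ".wig")))
  # per-bin GC fractions as a companion track: counts alone cannot be
  # GC-corrected downstream
  write_wig(binned_counts(grid, bc$gc),
            file.path("results/cohort", paste0(cohort$sample[i], ".gc.wig")))
}
write.table(cohort, "results/cohort/manifest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", nrow(cohort), "samples into results/cohort/",
    "(5e6 fragments each, seeded).\n")
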