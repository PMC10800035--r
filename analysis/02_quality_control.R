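#!/usr/bin/env Rscript
# Quality control of the simulated discovery cohort.
#
# Applies the standard pre-analysis filters: duplicate removal by
# identity-by-state, sex-discordance removal from X heterozygosity, then
# variant filters in the order missingness (> 5% removed), Hardy-Weinberg
# exact test (p < 1e-6 removed), and MAF (<= 0.01 removed). Cross-checks
# what was removed against the generator's injection registry.

suppressPackageStartupMessages(library(hetoa))

cohort_dir <- "results/cohort"
out <- "results/qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

g <- read_genotype_tsv(file.path(cohort_dir, "genotypes.tsv"))
samples <- read_sample_table(file.path(cohort_dir, "samples.tsv"))
truth <- jsonlite::read_json(file.path(cohort_dir, "truth.json"),
                             simplifyVector = TRUE)

res <- run_qc(g, samples, qc_config())
print(res$report)

write_table(qc_report_table(res$report), file.path(out, "qc_report.tsv"))
writeLines(unlist(res$report$removed_variant_ids),
           file.path(out, "removed_variants.txt"))
writeLines(unlist(res$report$removed_sample_ids),
           file.path(out, "removed_samples.txt"))
write_genotype_tsv(res$genotypes, file.path(out, "genotypes_qc.tsv"))
write_sample_table(res$samples, file.path(out, "samples_qc.tsv"))

# recall of the injected violations
hwe_recall <- mean(truth$hwe_variants %in% res$report$removed_variant_ids$hwe)
dup_removed <- res$report$removed_sample_ids$duplicate
dup_recall <- mean(apply(truth$duplicate_pairs, 1, function(pr)
  any(pr %in% dup_removed)))
sex_recall <- mean(truth$sex_swapped %in%
                     res$report$removed_sample_ids$sex_discordant)
message(sprintf(
  "injected-violation recall: HWE %.0f%%, duplicates %.0f%%, sex swaps %.0f%%",
  100 * hwe_recall, 100 * dup_recall, 100 * sex_recall))
stopifnot(hwe_recall == 1, dup_recall == 1)
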