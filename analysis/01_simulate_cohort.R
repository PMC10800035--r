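#!/usr/bin/env Rscript
# Build the discovery-design synthetic cohort.
#
# The study's raw genotype data are not publicly deposited, so every number
# downstream of this script is computed on a synthetic stand-in: 559 end-stage
# OA cases (172 hip / 387 knee) and 118 controls, genotyped at 5,000
# independent autosomal SNPs plus a sex-aware X block. Per-sample inbreeding
# F drives heterozygosity; higher heterozygosity is protective (true per-SD
# OR 0.65); age and BMI are weakly correlated with heterozygosity. A handful
# of QC violations (duplicates, sex swaps, heterozygote-deficit variants)
# are injected so the QC stage has something real to do.

suppressPackageStartupMessages(library(hetoa))

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_samples = 677, n_cases = 559, hip_fraction_of_cases = 172 / 559,
  n_snps = 5000, n_x_snps = 150,
  f_dist = list(law = "normal_truncated", mean = 0.02, sd = 0.015),
  beta_het = log(0.65),
  cov_f_age = -0.089, cov_f_bmi = 0.091,
  missing_rate = 0.005,
  n_hwe_violations = 8, n_duplicates = 2, n_sex_swaps = 2,
  seed = 20260922L)

co <- generate_cohort(cfg)

write_genotype_tsv(co$genotypes, file.path(out, "genotypes.tsv"))
write_sample_table(co$samples, file.path(out, "samples.tsv"))
jsonlite::write_json(
  list(seed = co$truth$seed, beta_het = co$truth$beta_het,
       beta0 = co$truth$beta0,
       sample_id = co$samples$sample_id[seq_along(co$truth$f)],
       f = co$truth$f,
       hwe_variants = co$truth$hwe_variants,
       duplicate_pairs = co$truth$duplicate_pairs,
       sex_swapped = co$truth$sex_swapped),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)

message(sprintf(
  "cohort: %d samples (%d cases / %d controls) x %d variants; injected %d HWE violations, %d duplicates, %d sex swaps",
  length(co$genotypes$samples),
  sum(co$samples$status == "case"), sum(co$samples$status == "control"),
  nrow(co$genotypes$variants),
  length(co$truth$hwe_variants), nrow(co$truth$duplicate_pairs),
  length(co$truth$sex_swapped)))
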