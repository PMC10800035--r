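#' Pipeline configuration
#'
#' Describes one full analysis run: where the cohort comes from (files or a
#' simulation config — exactly one), the QC thresholds, heterozygosity
#' options, covariate list and output directory.
#'
#' @param genotype_tsv,sample_tsv,vcf input files; supply either
#'   `genotype_tsv` + `sample_tsv` or `vcf` + `sample_tsv`.
#' @param simulation a [sim_config()] as the cohort source instead of files.
#' @param qc a [qc_config()].
#' @param strata increasing MAF thresholds, each in `[0, 0.5)`; default the
#'   two conventional strata 0.01 and 0.1.
#' @param denominator,small_sample_correction heterozygosity options, see
#'   [compute_het_profiles()].
#' @param covariates covariate names for [association_test()]; the
#'   covariate-adjusted design uses `c("age", "sex", "bmi")`, the
#'   no-covariate design `character()`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest (and used when
#'   `simulation` carries no seed of its own).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype_tsv = NULL, sample_tsv = NULL,
                            vcf = NULL, simulation = NULL,
                            qc = qc_config(),
                            strata = c(0.01, 0.1),
                            denominator = "hom_alt",
                            small_sample_correction = TRUE,
                            covariates = c("age", "sex", "bmi"),
                            out_dir = "results",
                            seed = 1L) {
  from_files <- !is.null(sample_tsv) && (!is.null(genotype_tsv) || !is.null(vcf))
  from_sim <- !is.null(simulation)
  if (from_files == from_sim) {
    stop("supply exactly one cohort source: input files or a simulation config")
  }
  if (any(diff(strata) <= 0) || any(strata < 0 | strata >= 0.5)) {
    stop("strata must be strictly increasing, each in [0, 0.5)")
  }
  cfg <- as.list(environment())[c(
    "genotype_tsv", "sample_tsv", "vcf", "simulation", "qc", "strata",
    "denominator", "small_sample_correction", "covariates", "out_dir",
    "seed")]
  class(cfg) <- "pipeline_config"
  cfg
}

#' Study-design presets
#'
#' `"discovery"` is a covariate-adjusted discovery design (559 cases, 172 of them
#' hip, 118 controls; age/sex/BMI adjustment); `"replication"` is a large
#' all-female unadjusted design (2,019 cases, 2,029 controls, no covariate
#' data). SNP counts are desk-scale.
#'
#' @param preset `"discovery"` or `"replication"`.
#' @param seed integer seed.
#' @param n_snps autosomal SNP count override.
#' @return a [pipeline_config()].
#' @export
preset_config <- function(preset = c("discovery", "replication"), seed = 1L,
                          n_snps = 5000) {
  preset <- match.arg(preset)
  if (preset == "discovery") {
    sim <- sim_config(n_samples = 677, n_cases = 559,
                      hip_fraction_of_cases = 172 / 559,
                      n_snps = n_snps, seed = seed)
    pipeline_config(simulation = sim, covariates = c("age", "sex", "bmi"),
                    seed = seed)
  } else {
    sim <- sim_config(n_samples = 4048, n_cases = 2019,
                      hip_fraction_of_cases = 0.5, n_snps = n_snps,
                      pct_female = 1, seed = seed)
    pipeline_config(simulation = sim, covariates = character(), seed = seed)
  }
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the cohort, runs QC, computes heterozygosity profiles
#' for every configured MAF stratum, fits the metric x stratum x subgroup
#' association grid, and writes `qc_report.tsv`, `het_profiles.tsv`,
#' `association.tsv`, `cohort_summary.tsv` and `run_manifest.json` to the
#' output directory. Progress is reported via messages.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `qc`, `profiles` (named by stratum label),
#'   `association`, `summary`, `out_dir`, and `truth` when simulating.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$simulation)) {
    message("simulating cohort (seed ", config$simulation$seed, ")")
    cohort <- generate_cohort(config$simulation)
    g <- cohort$genotypes; samples <- cohort$samples; truth <- cohort$truth
  } else {
    message("reading cohort from files")
    g <- if (!is.null(config$vcf)) read_vcf(config$vcf)
         else read_genotype_tsv(config$genotype_tsv)
    samples <- read_sample_table(config$sample_tsv)
  }
  message("cohort: ", length(g$samples), " samples x ",
          nrow(g$variants), " variants")

  qcres <- run_qc(g, samples, config$qc)
  message("QC: ", qcres$report$n_samples_out, " samples, ",
          qcres$report$n_variants_out, " variants retained")
  write_table(qc_report_table(qcres$report),
              file.path(config$out_dir, "qc_report.tsv"))
  writeLines(unlist(qcres$report$removed_variant_ids),
             file.path(config$out_dir, "removed_variants.txt"))
  writeLines(unlist(qcres$report$removed_sample_ids),
             file.path(config$out_dir, "removed_samples.txt"))

  freqs <- allele_frequencies(autosomal(qcres$genotypes))
  profiles <- lapply(config$strata, function(th) {
    compute_het_profiles(qcres$genotypes, maf_threshold = th,
                         denominator = config$denominator,
                         small_sample_correction = config$small_sample_correction,
                         freqs = freqs)
  })
  names(profiles) <- vapply(config$strata, stratum_label, character(1))
  write_table(do.call(rbind, profiles),
              file.path(config$out_dir, "het_profiles.tsv"))

  assoc <- analysis_grid(profiles, qcres$samples,
                         covariates = config$covariates)
  write_table(assoc, file.path(config$out_dir, "association.tsv"))
  message("association grid: ", nrow(assoc), " cells")

  summ <- cohort_summary(qcres$samples)
  write_table(summ$groups, file.path(config$out_dir, "cohort_summary.tsv"))
  write_table(summ$tests,
              file.path(config$out_dir, "cohort_summary_tests.tsv"))

  manifest <- list(
    seed = config$seed,
    strata = config$strata,
    covariates = config$covariates,
    denominator = config$denominator,
    small_sample_correction = config$small_sample_correction,
    qc_thresholds = config$qc[c("maf_min", "miss_max", "hwe_alpha",
                                "ibs_min")],
    simulated = !is.null(config$simulation),
    n_samples_out = qcres$report$n_samples_out,
    n_variants_out = qcres$report$n_variants_out,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(qc = qcres, profiles = profiles, association = assoc,
                 summary = summ, out_dir = config$out_dir, truth = truth))
}
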