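#' Per-sample genotype counts
#'
#' Counts heterozygous, homozygous-reference, homozygous-alternative and
#' missing calls per sample over the autosomal variants of `g`. Samples with
#' zero non-missing calls are flagged (column `degenerate`) and should be
#' excluded from downstream rates.
#'
#' @param g a [genotype_matrix()]; restricted internally to autosomes.
#' @return data.frame with columns `sample_id`, `n_het`, `n_hom_ref`,
#'   `n_hom_alt`, `n_missing`, `degenerate`.
#' @export
genotype_counts <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  ga <- autosomal(g)
  calls <- ga$calls
  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  n_hom_ref <- rowSums(calls == 0L, na.rm = TRUE)
  n_hom_alt <- rowSums(calls == 2L, na.rm = TRUE)
  n_missing <- rowSums(is.na(calls))
  degenerate <- (n_het + n_hom_ref + n_hom_alt) == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " sample(s) with no non-missing autosomal ",
            "calls flagged for exclusion")
  }
  data.frame(sample_id = ga$samples,
             n_het = as.integer(n_het),
             n_hom_ref = as.integer(n_hom_ref),
             n_hom_alt = as.integer(n_hom_alt),
             n_missing = as.integer(n_missing),
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Heterozygote-to-homozygote ratio (HetRate)
#'
#' The per-individual heterozygosity rate: the number of heterozygote
#' genotypes divided, by default, by the number of homozygote genotypes for
#' the alternative allele. `denominator = "hom_all"` instead divides by all
#' homozygote genotypes, the convention of most per-sample heterozygosity
#' tooling.
#'
#' @param n_het,n_hom_alt,n_hom_ref per-sample genotype counts (vectorised).
#' @param denominator `"hom_alt"` (default) or `"hom_all"`.
#' @return numeric vector; `NA` with a warning where the denominator is 0.
#' @export
het_rate <- function(n_het, n_hom_alt, n_hom_ref = NULL,
                     denominator = c("hom_alt", "hom_all")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "hom_alt") {
    n_hom_alt
  } else {
    if (is.null(n_hom_ref)) stop("denominator 'hom_all' needs n_hom_ref")
    n_hom_alt + n_hom_ref
  }
  out <- ifelse(den > 0, n_het / den, NA_real_)
  if (any(den == 0)) {
    warning(sum(den == 0), " sample(s) have zero ", denominator,
            " genotypes: HetRate undefined, excluded")
  }
  out
}

#' Per-sample expected heterozygosity
#'
#' For sample i, the mean over its non-missing autosomal variants j of
#' u_j = 2 p_j (1 - p_j), where p_j is the cohort alt-allele frequency.
#' With `small_sample_correction` (default on, matching standard per-sample
#' expected-homozygosity tooling) each u_j is multiplied by
#' 2N_j / (2N_j - 1), with N_j the number of samples called at j, which
#' removes the downward bias of the plug-in frequency estimate. Monomorphic
#' variants contribute 0.
#'
#' @param g a [genotype_matrix()] (autosomes used).
#' @param freqs [allele_frequencies()] computed on the same post-QC cohort;
#'   defaults to frequencies of `g`.
#' @param small_sample_correction logical; default `TRUE`.
#' @return named numeric vector of h_exp per sample.
#' @export
expected_het <- function(g, freqs = NULL, small_sample_correction = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  ga <- autosomal(g)
  if (is.null(freqs)) freqs <- allele_frequencies(ga)
  fi <- match(ga$variants$variant_id, freqs$variant_id)
  if (anyNA(fi)) stop("freqs does not cover all autosomal variants of g")
  p <- freqs$p_alt[fi]
  u <- 2 * p * (1 - p)
  if (small_sample_correction) {
    nn <- freqs$n_called[fi]
    corr <- ifelse(nn > 0, 2 * nn / (2 * nn - 1), NA_real_)
    u <- u * corr
  }
  u[is.na(u)] <- 0  # variants with no frequency contribute nothing
  called <- !is.na(ga$calls)
  num <- as.vector(called %*% u)
  den <- rowSums(called)
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- ga$samples
  out
}

#' Heterozygosity excess
#'
#' Relative excess of observed over expected heterozygosity,
#' (h_obs - h_exp) / h_exp. Algebraically this equals the negative of the
#' method-of-moments inbreeding estimate F-hat = 1 - h_obs / h_exp, so a
#' more inbred individual has a more negative HetExcess.
#'
#' @param h_obs,h_exp observed and expected heterozygosity rates
#'   (vectorised); `h_exp` must be positive where defined.
#' @return numeric vector; `NA` with a warning where `h_exp` is 0.
#' @export
het_excess <- function(h_obs, h_exp) {
  bad <- !is.na(h_exp) & h_exp == 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) have zero expected heterozygosity: ",
            "HetExcess undefined, excluded")
  }
  ifelse(bad, NA_real_, (h_obs - h_exp) / h_exp)
}

#' Standardize to z-scores
#'
#' Centers and scales by the sample standard deviation (n - 1 denominator).
#' `NA` values are carried through; mean and SD come from the non-missing
#' values.
#'
#' @param values numeric vector with at least 2 finite values and nonzero
#'   spread.
#' @return z-scored vector with mean 0 and sample SD 1 over the non-missing
#'   entries.
#' @export
zscore <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least 2 finite values to standardize")
  s <- stats::sd(v)
  if (s == 0) stop("cannot standardize constant vector")
  (values - mean(v)) / s
}

#' Per-sample heterozygosity profiles at a MAF stratum
#'
#' Restricts to autosomal variants with cohort MAF strictly above
#' `maf_threshold`, computes per-sample genotype counts, observed and
#' expected heterozygosity, HetRate and HetExcess, then z-scores both
#' metrics across all retained samples (cases and controls together).
#' Samples for which either metric is undefined (zero denominator) are
#' dropped from the profile table so both metrics share one analysis set.
#'
#' @param g a post-QC [genotype_matrix()].
#' @param maf_threshold stratum lower bound; the conventional strata are
#'   0.01 and 0.1.
#' @param denominator HetRate denominator mode, see [het_rate()].
#' @param small_sample_correction see [expected_het()].
#' @param freqs optional precomputed [allele_frequencies()] on the autosomal
#'   variants of `g`.
#' @return data.frame (one row per retained sample) with columns
#'   `sample_id`, `stratum`, `n_het`, `n_hom_ref`, `n_hom_alt`, `n_missing`,
#'   `h_obs`, `h_exp`, `het_rate`, `het_excess`, `z_het_rate`,
#'   `z_het_excess`.
#' @export
compute_het_profiles <- function(g, maf_threshold = 0.01,
                                 denominator = c("hom_alt", "hom_all"),
                                 small_sample_correction = TRUE,
                                 freqs = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  denominator <- match.arg(denominator)
  ga <- autosomal(g)
  if (nrow(ga$variants) == 0) stop("no autosomal variants")
  if (is.null(freqs)) freqs <- allele_frequencies(ga)
  keep <- !is.na(freqs$maf) & freqs$maf > maf_threshold
  gs <- subset_genotypes(ga, variants = which(keep))
  if (nrow(gs$variants) == 0) {
    stop("no variants above MAF threshold ", maf_threshold)
  }
  fs <- freqs[keep, , drop = FALSE]

  counts <- genotype_counts(gs)
  n_called <- counts$n_het + counts$n_hom_ref + counts$n_hom_alt
  h_obs <- ifelse(n_called > 0, counts$n_het / n_called, NA_real_)
  h_exp <- expected_het(gs, fs,
                        small_sample_correction = small_sample_correction)
  hr <- het_rate(counts$n_het, counts$n_hom_alt, counts$n_hom_ref,
                 denominator = denominator)
  hx <- het_excess(h_obs, h_exp)

  stratum <- stratum_label(maf_threshold)
  prof <- data.frame(
    sample_id = counts$sample_id,
    stratum = stratum,
    n_het = counts$n_het,
    n_hom_ref = counts$n_hom_ref,
    n_hom_alt = counts$n_hom_alt,
    n_missing = counts$n_missing,
    h_obs = h_obs,
    h_exp = unname(h_exp),
    het_rate = hr,
    het_excess = hx,
    stringsAsFactors = FALSE
  )
  ok <- !counts$degenerate & !is.na(prof$het_rate) & !is.na(prof$het_excess)
  if (any(!ok)) {
    message("compute_het_profiles: dropping ", sum(!ok),
            " sample(s) with undefined statistics")
  }
  prof <- prof[ok, , drop = FALSE]
  if (nrow(prof) < 2) stop("fewer than 2 samples with defined statistics")
  prof$z_het_rate <- zscore(prof$het_rate)
  prof$z_het_excess <- zscore(prof$het_excess)
  rownames(prof) <- NULL
  prof
}

# canonical stratum labels for the two conventional thresholds
stratum_label <- function(maf_threshold) {
  if (isTRUE(all.equal(maf_threshold, 0.01))) return("maf_gt_001")
  if (isTRUE(all.equal(maf_threshold, 0.1))) return("maf_gt_01")
  paste0("maf_gt_", gsub("[.]", "", format(maf_threshold)))
}
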