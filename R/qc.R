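#' Per-variant allele frequencies
#'
#' Computes the alt-allele frequency and minor allele frequency of every
#' variant from non-missing calls. Variants with no non-missing call get
#' `NA` frequencies (they fail all downstream frequency filters).
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with columns `variant_id`, `p_alt`, `maf`, `n_called`.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_called <- colSums(!is.na(g$calls))
  alt_sum <- colSums(g$calls, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt_sum / (2 * n_called), NA_real_)
  data.frame(
    variant_id = g$variants$variant_id,
    p_alt = p_alt,
    maf = pmin(p_alt, 1 - p_alt),
    n_called = as.integer(n_called),
    stringsAsFactors = FALSE
  )
}

#' Filter variants by minor allele frequency
#'
#' Retains variants with MAF strictly greater than `maf_min` (so variants at
#' or below the threshold, and variants with undefined frequency, are
#' removed).
#'
#' @param g a [genotype_matrix()].
#' @param freqs frequency table from [allele_frequencies()] computed on `g`.
#' @param maf_min MAF threshold in `[0, 0.5)`; default 0.01.
#' @return list with `genotypes` (filtered matrix) and `removed` (variant
#'   ids).
#' @export
filter_maf <- function(g, freqs = allele_frequencies(g), maf_min = 0.01) {
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min >= 0.5) {
    stop("maf_min must be in [0, 0.5)")
  }
  keep <- !is.na(freqs$maf) & freqs$maf > maf_min
  list(genotypes = subset_genotypes(g, variants = which(keep)),
       removed = g$variants$variant_id[!keep])
}

#' Filter variants by missing-call rate
#'
#' Removes variants whose fraction of missing calls strictly exceeds
#' `miss_max`; a variant exactly at the threshold is retained.
#'
#' @param g a [genotype_matrix()].
#' @param miss_max maximum tolerated missing fraction in `[0, 1]`;
#'   default 0.05.
#' @return list with `genotypes` and `removed` as in [filter_maf()].
#' @export
filter_missingness <- function(g, miss_max = 0.05) {
  if (!is.numeric(miss_max) || miss_max < 0 || miss_max > 1) {
    stop("miss_max must be in [0, 1]")
  }
  rate <- colMeans(is.na(g$calls))
  keep <- rate <= miss_max
  list(genotypes = subset_genotypes(g, variants = which(keep)),
       removed = g$variants$variant_id[!keep])
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on a single variant's genotype counts.
#' Conditional on the observed allele counts, the probability of every
#' attainable heterozygote count (same parity as the minor-allele count) is
#' computed by the standard log-space recurrence, and the p-value is the sum
#' of probabilities no larger than that of the observed count. No mid-p
#' adjustment.
#'
#' All three arguments are vectorised in parallel.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (each >= 0, total >= 1).
#' @return p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  n_hom_ref <- rep_len(as.integer(n_hom_ref), n)
  n_het <- rep_len(as.integer(n_het), n)
  n_hom_alt <- rep_len(as.integer(n_hom_alt), n)
  if (any(n_hom_ref < 0 | n_het < 0 | n_hom_alt < 0, na.rm = TRUE)) {
    stop("genotype counts must be non-negative")
  }
  if (any(n_hom_ref + n_het + n_hom_alt < 1, na.rm = TRUE)) {
    stop("total genotype count must be at least 1")
  }
  vapply(seq_len(n), function(i) {
    hwe_exact_one(n_hom_ref[i], n_het[i], n_hom_alt[i])
  }, numeric(1))
}

# single-variant exact test; log-space recurrence over heterozygote counts
hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  if (is.na(n_aa) || is.na(n_ab) || is.na(n_bb)) return(NA_real_)
  n <- n_aa + n_ab + n_bb
  n_alt <- 2L * n_bb + n_ab
  n_rare <- min(n_alt, 2L * n - n_alt)
  if (n_rare == 0L) return(1.0)  # monomorphic: single configuration

  hs <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  logp <- numeric(length(hs))
  # unnormalised log-probabilities via the ratio
  #   P(h+2)/P(h) = 4 * n_hom_rare(h) * n_hom_common(h) / ((h+2)(h+1))
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1L]
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    logp[k] <- logp[k - 1L] +
      log(4) + log(hom_rare) + log(hom_common) - log(h + 2) - log(h + 1)
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- match(n_ab, hs)
  if (is.na(obs)) stop("observed heterozygote count has impossible parity")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Filter variants violating Hardy-Weinberg equilibrium
#'
#' Removes variants whose HWE exact-test p-value falls below `hwe_alpha`.
#' Genotype counts can be taken over all samples (default) or over controls
#' only.
#'
#' @param g a [genotype_matrix()].
#' @param hwe_alpha significance threshold in (0, 1); default 1e-6.
#' @param scope `"all"` or `"controls"`.
#' @param samples a [sample_table()]; required when `scope = "controls"`.
#' @return list with `genotypes` and `removed` as in [filter_maf()].
#' @export
filter_hwe <- function(g, hwe_alpha = 1e-6, scope = c("all", "controls"),
                       samples = NULL) {
  if (!is.numeric(hwe_alpha) || hwe_alpha <= 0 || hwe_alpha >= 1) {
    stop("hwe_alpha must be in (0, 1)")
  }
  scope <- match.arg(scope)
  gg <- g
  if (scope == "controls") {
    if (is.null(samples)) stop("scope = 'controls' requires a sample table")
    ctrl <- samples$sample_id[samples$status == "control"]
    gg <- subset_genotypes(g, samples = intersect(g$samples, ctrl))
  }
  n_ref <- colSums(gg$calls == 0L, na.rm = TRUE)
  n_het <- colSums(gg$calls == 1L, na.rm = TRUE)
  n_alt <- colSums(gg$calls == 2L, na.rm = TRUE)
  total <- n_ref + n_het + n_alt
  p <- rep(NA_real_, length(total))
  ok <- total >= 1
  p[ok] <- hwe_exact_test(n_ref[ok], n_het[ok], n_alt[ok])
  keep <- is.na(p) | p >= hwe_alpha
  keep[!ok] <- FALSE  # no data at all: fails QC
  list(genotypes = subset_genotypes(g, variants = which(keep)),
       removed = g$variants$variant_id[!keep])
}

#' Find duplicate samples by identity-by-state
#'
#' Computes pairwise IBS (fraction of identical genotype codes over mutually
#' non-missing variants) and reports pairs at or above `ibs_min`. Pairs with
#' fewer than 50 overlapping variants are skipped with a warning. For large
#' variant counts a deterministic subset of variants is used to screen out
#' clearly unrelated pairs before exact IBS is computed.
#'
#' @param g a [genotype_matrix()] with at least 2 samples (1 sample gives an
#'   empty result).
#' @param ibs_min IBS threshold in (0, 1]; default 0.95.
#' @return data.frame with columns `sample_1`, `sample_2`, `ibs`,
#'   `n_overlap`; zero rows when no pair qualifies.
#' @export
find_duplicates <- function(g, ibs_min = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  empty <- data.frame(sample_1 = character(), sample_2 = character(),
                      ibs = numeric(), n_overlap = integer(),
                      stringsAsFactors = FALSE)
  ns <- length(g$samples)
  if (ns < 2) return(empty)

  match_counts <- function(calls) {
    m <- !is.na(calls)
    shared <- tcrossprod(m * 1)
    eq <- matrix(0, nrow(calls), nrow(calls))
    for (code in 0:2) {
      a <- (calls == code) & m
      eq <- eq + tcrossprod(a * 1)
    }
    list(eq = eq, shared = shared)
  }

  nv <- nrow(g$variants)
  cand <- NULL
  if (nv > 600) {
    # screen on an evenly spaced subset; generous margin below ibs_min
    idx <- unique(round(seq(1, nv, length.out = 400)))
    sc <- match_counts(g$calls[, idx, drop = FALSE])
    ibs_s <- ifelse(sc$shared > 0, sc$eq / sc$shared, 0)
    cand <- which(ibs_s >= ibs_min - 0.1 & upper.tri(ibs_s), arr.ind = TRUE)
    if (nrow(cand) == 0) return(empty)
    keep_samples <- sort(unique(c(cand[, 1], cand[, 2])))
    sub <- match_counts(g$calls[keep_samples, , drop = FALSE])
    eq <- sub$eq; shared <- sub$shared
    idx_map <- keep_samples
  } else {
    fc <- match_counts(g$calls)
    eq <- fc$eq; shared <- fc$shared
    idx_map <- seq_len(ns)
  }

  pairs <- which(upper.tri(shared), arr.ind = TRUE)
  out <- data.frame(
    i = idx_map[pairs[, 1]], j = idx_map[pairs[, 2]],
    ibs = ifelse(shared[pairs] > 0, eq[pairs] / shared[pairs], NA_real_),
    n_overlap = as.integer(shared[pairs])
  )
  thin <- out$n_overlap < 50
  if (any(thin)) {
    warning(sum(thin), " sample pair(s) skipped: fewer than 50 overlapping ",
            "variants makes IBS unreliable")
  }
  out <- out[!thin & !is.na(out$ibs) & out$ibs >= ibs_min, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  data.frame(sample_1 = g$samples[out$i], sample_2 = g$samples[out$j],
             ibs = out$ibs, n_overlap = out$n_overlap,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag sex-discordant samples from X-chromosome heterozygosity
#'
#' Males are hemizygous on X, so genotype callers emit (almost) no X
#' heterozygotes for them; females show ordinary heterozygosity. A recorded
#' female with X het rate below `x_het_female_min`, or a recorded male above
#' `x_het_male_max`, is flagged as discordant. Samples without recorded sex
#' or without called X genotypes are skipped.
#'
#' @param g a [genotype_matrix()] containing X-chromosome variants.
#' @param samples a [sample_table()] with recorded sex.
#' @param x_het_female_min minimum plausible female X het rate; default 0.05.
#' @param x_het_male_max maximum plausible male X het rate; default 0.10.
#' @return character vector of discordant sample ids (possibly empty).
#' @export
check_sex <- function(g, samples, x_het_female_min = 0.05,
                      x_het_male_max = 0.10) {
  xi <- which(is_x_chrom(g$variants$chrom))
  if (length(xi) == 0) {
    warning("no X-chromosome variants: sex check skipped")
    return(character())
  }
  xc <- g$calls[, xi, drop = FALSE]
  n_called <- rowSums(!is.na(xc))
  het_rate <- ifelse(n_called > 0, rowSums(xc == 1L, na.rm = TRUE) / n_called,
                     NA_real_)
  sex <- samples$sex[match(g$samples, samples$sample_id)]
  usable <- !is.na(sex) & !is.na(het_rate)
  if (any(!usable)) {
    warning(sum(!usable), " sample(s) skipped in sex check (no recorded sex ",
            "or no called X genotypes)")
  }
  flagged <- usable &
    ((sex == "female" & het_rate < x_het_female_min) |
       (sex == "male" & het_rate > x_het_male_max))
  g$samples[flagged]
}

#' Default QC thresholds
#'
#' @param maf_min minimum MAF (strictly greater retained); default 0.01.
#' @param miss_max maximum missing-call rate; default 0.05.
#' @param hwe_alpha HWE exact-test threshold; default 1e-6.
#' @param hwe_scope `"all"` or `"controls"`.
#' @param ibs_min duplicate IBS threshold; default 0.95.
#' @param x_het_female_min,x_het_male_max sex-check thresholds.
#' @param exclude_samples optional user-supplied sample ids to drop first
#'   (e.g. population-structure outliers identified externally).
#' @return list of thresholds for [run_qc()].
#' @export
qc_config <- function(maf_min = 0.01, miss_max = 0.05, hwe_alpha = 1e-6,
                      hwe_scope = "all", ibs_min = 0.95,
                      x_het_female_min = 0.05, x_het_male_max = 0.10,
                      exclude_samples = character()) {
  list(maf_min = maf_min, miss_max = miss_max, hwe_alpha = hwe_alpha,
       hwe_scope = hwe_scope, ibs_min = ibs_min,
       x_het_female_min = x_het_female_min, x_het_male_max = x_het_male_max,
       exclude_samples = exclude_samples)
}

#' Run the full QC procedure
#'
#' Applies, in order: user exclusion list, duplicate removal (keeping the
#' member of each pair with fewer missing calls, ties broken by sample id),
#' sex-discordance removal, then variant filters missingness -> HWE -> MAF
#' with allele frequencies recomputed on the post-sample-QC cohort. Variant
#' filters act on autosomal variants; X/Y/MT variants are carried through
#' unfiltered (downstream heterozygosity uses autosomes only).
#'
#' @param g a [genotype_matrix()].
#' @param samples a [sample_table()] covering the samples of `g`.
#' @param config thresholds from [qc_config()].
#' @return list with `genotypes`, `samples`, and `report` (see
#'   [qc_report_table()] for the tabular form). The report records counts
#'   in/out, per-filter removals, thresholds, and the removed ids.
#' @export
run_qc <- function(g, samples, config = qc_config()) {
  stopifnot(inherits(g, "genotype_matrix"))
  samples <- sample_table(as.data.frame(samples))
  n_samples_in <- length(g$samples)
  n_variants_in <- nrow(g$variants)

  removed_samples <- list(excluded = character(), duplicate = character(),
                          sex_discordant = character())

  if (length(config$exclude_samples) > 0) {
    removed_samples$excluded <- intersect(g$samples, config$exclude_samples)
    g <- subset_genotypes(g, samples = setdiff(g$samples, removed_samples$excluded))
  }

  dups <- find_duplicates(g, ibs_min = config$ibs_min)
  if (nrow(dups) > 0) {
    n_miss <- rowSums(is.na(g$calls))
    names(n_miss) <- g$samples
    drop <- character()
    for (k in seq_len(nrow(dups))) {
      a <- dups$sample_1[k]; b <- dups$sample_2[k]
      if (a %in% drop || b %in% drop) next
      # keep the sample with fewer missing calls; tie -> keep smaller id
      worse <- if (n_miss[a] != n_miss[b]) {
        if (n_miss[a] > n_miss[b]) a else b
      } else {
        max(a, b)
      }
      drop <- c(drop, worse)
    }
    removed_samples$duplicate <- drop
    g <- subset_genotypes(g, samples = setdiff(g$samples, drop))
  }

  has_x <- any(is_x_chrom(g$variants$chrom))
  has_sex <- any(!is.na(samples$sex[match(g$samples, samples$sample_id)]))
  if (has_x && has_sex) {
    disc <- check_sex(g, samples,
                      x_het_female_min = config$x_het_female_min,
                      x_het_male_max = config$x_het_male_max)
    removed_samples$sex_discordant <- disc
    g <- subset_genotypes(g, samples = setdiff(g$samples, disc))
  }
  if (length(g$samples) == 0) stop("QC removed everything: no samples left")

  auto <- is_autosome(g$variants$chrom)
  non_auto_ids <- g$variants$variant_id[!auto]
  ga <- subset_genotypes(g, variants = which(auto))

  f1 <- filter_missingness(ga, miss_max = config$miss_max)
  f2 <- filter_hwe(f1$genotypes, hwe_alpha = config$hwe_alpha,
                   scope = config$hwe_scope, samples = samples)
  f3 <- filter_maf(f2$genotypes, allele_frequencies(f2$genotypes),
                   maf_min = config$maf_min)
  if (nrow(f3$genotypes$variants) == 0) {
    stop("QC removed everything: no autosomal variants left")
  }

  keep_ids <- c(f3$genotypes$variants$variant_id, non_auto_ids)
  g_out <- subset_genotypes(
    g, variants = which(g$variants$variant_id %in% keep_ids))
  s_out <- samples[samples$sample_id %in% g_out$samples, , drop = FALSE]
  class(s_out) <- c("sample_table", "data.frame")

  report <- list(
    n_samples_in = n_samples_in,
    n_samples_out = length(g_out$samples),
    n_variants_in = n_variants_in,
    n_variants_out = nrow(g_out$variants),
    removed_excluded_samples = length(removed_samples$excluded),
    removed_duplicate_samples = length(removed_samples$duplicate),
    removed_sex_discordant = length(removed_samples$sex_discordant),
    removed_by_missingness = length(f1$removed),
    removed_by_hwe = length(f2$removed),
    removed_by_maf = length(f3$removed),
    thresholds = config[c("maf_min", "miss_max", "hwe_alpha", "ibs_min")],
    removed_variant_ids = list(missingness = f1$removed, hwe = f2$removed,
                               maf = f3$removed),
    removed_sample_ids = removed_samples
  )
  class(report) <- "qc_report"
  list(genotypes = g_out, samples = s_out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  samples:  ", x$n_samples_in, " -> ", x$n_samples_out,
      " (duplicates ", x$removed_duplicate_samples,
      ", sex-discordant ", x$removed_sex_discordant,
      ", excluded ", x$removed_excluded_samples, ")\n", sep = "")
  cat("  variants: ", x$n_variants_in, " -> ", x$n_variants_out,
      " (missingness ", x$removed_by_missingness,
      ", HWE ", x$removed_by_hwe,
      ", MAF ", x$removed_by_maf, ")\n", sep = "")
  invisible(x)
}

#' Tabular form of a QC report
#'
#' One row per filter with its threshold and removal count, suitable for
#' [write_table()].
#'
#' @param report the `report` element returned by [run_qc()].
#' @return data.frame with columns `filter`, `threshold`, `n_removed`.
#' @export
qc_report_table <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  data.frame(
    filter = c("excluded_samples", "duplicate_samples", "sex_discordant",
               "missingness", "hwe", "maf"),
    threshold = c(NA, report$thresholds$ibs_min, NA,
                  report$thresholds$miss_max, report$thresholds$hwe_alpha,
                  report$thresholds$maf_min),
    n_removed = c(report$removed_excluded_samples,
                  report$removed_duplicate_samples,
                  report$removed_sex_discordant,
                  report$removed_by_missingness,
                  report$removed_by_hwe,
                  report$removed_by_maf),
    stringsAsFactors = FALSE
  )
}
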