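#' Genotype matrix container
#'
#' A `genotype_matrix` holds biallelic genotype calls for a cohort as
#' alt-allele counts. Calls are stored as an integer matrix (samples in rows,
#' variants in columns) with values 0 (hom ref), 1 (het), 2 (hom alt) and
#' `NA` for missing. Missing calls are always `NA`, never a numeric code, so
#' they can never leak into arithmetic.
#'
#' @param calls integer matrix, samples x variants, values in {0, 1, 2, NA}.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`; one row per column of `calls`.
#' @param samples character vector of unique sample ids, one per row of
#'   `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants`, `samples`. Row/column names of `calls` are set to
#'   the sample and variant ids.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.character(samples)

  needed <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(variants))) {
    stop("variants must have columns: ", paste(needed, collapse = ", "))
  }
  variants$variant_id <- as.character(variants$variant_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)

  if (nrow(calls) != length(samples)) {
    stop("calls has ", nrow(calls), " rows but ", length(samples), " samples")
  }
  if (ncol(calls) != nrow(variants)) {
    stop("calls has ", ncol(calls), " columns but ", nrow(variants), " variants")
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant ids: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  }
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  if (any(!is.na(variants$pos) & variants$pos < 1)) stop("pos must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")

  dimnames(calls) <- list(samples, variants$variant_id)
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_auto <- sum(is_autosome(x$variants$chrom))
  cat("genotype_matrix: ", length(x$samples), " samples x ",
      nrow(x$variants), " variants (", n_auto, " autosomal)\n", sep = "")
  cat("missing calls: ", sum(is.na(x$calls)), " (",
      format(100 * mean(is.na(x$calls)), digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# chromosome classification; tolerant of "chr" prefixes
is_autosome <- function(chrom) {
  c2 <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  c2 %in% as.character(1:22)
}

is_x_chrom <- function(chrom) {
  c2 <- toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
  c2 %in% c("X", "23")
}

#' Subset a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param samples,variants character ids or logical/integer index vectors;
#'   `NULL` keeps everything.
#' @return A new `genotype_matrix` restricted to the requested samples and
#'   variants, order following the index vectors.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(g$samples) else {
    if (is.character(samples)) match(samples, g$samples) else samples
  }
  vi <- if (is.null(variants)) seq_len(nrow(g$variants)) else {
    if (is.character(variants)) match(variants, g$variants$variant_id) else variants
  }
  if (is.numeric(si) && anyNA(si)) stop("unknown sample id in subset")
  if (is.numeric(vi) && anyNA(vi)) stop("unknown variant id in subset")
  genotype_matrix(g$calls[si, vi, drop = FALSE],
                  g$variants[vi, , drop = FALSE],
                  g$samples[si])
}

#' Restrict a genotype matrix to autosomal variants
#'
#' @param g a [genotype_matrix()].
#' @return A `genotype_matrix` containing only variants on chromosomes 1-22.
#' @export
autosomal <- function(g) {
  subset_genotypes(g, variants = which(is_autosome(g$variants$chrom)))
}
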