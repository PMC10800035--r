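# quick fixture builders

# genotype matrix from a bare call matrix; autosomal chrom labels by default
make_gm <- function(calls, chrom = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- as.character(rep_len(1:22, m))
  genotype_matrix(
    calls,
    data.frame(variant_id = sprintf("v%03d", seq_len(m)),
               chrom = chrom, pos = seq_len(m), ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    sprintf("S%03d", seq_len(nrow(calls))))
}

# sample table with sensible defaults
make_samples <- function(n_case, n_control, joint = NULL, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  status <- c(rep("case", n_case), rep("control", n_control))
  if (is.null(joint)) {
    joint <- ifelse(status == "case",
                    sample(c("hip", "knee"), n, replace = TRUE), "none")
  }
  sample_table(data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    status = status, joint = joint,
    age = round(rnorm(n, 62, 9), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    bmi = round(rnorm(n, 32, 6), 1),
    diabetes = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.15, 0.85)),
    stringsAsFactors = FALSE))
}

# random call matrix with missingness, under HWE at uniform frequencies
random_gm <- function(n, m, miss = 0.05, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  calls <- sapply(p, function(pp) {
    g <- rbinom(n, 2, pp)
    g[runif(n) < miss] <- NA
    g
  })
  make_gm(matrix(as.integer(calls), nrow = n))
}

# minimal VCF text for read_vcf tests
write_test_vcf <- function(path, gts, chrom = NULL, ref = NULL, alt = NULL) {
  m <- nrow(gts)  # variants in rows, samples in columns
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gts)), collapse = "\t"))
  body <- vapply(seq_len(m), function(i) {
    paste(c(chrom[i], i * 100, paste0("rs", i), ref[i], alt[i], ".", "PASS",
            ".", "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
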