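#' Read genotypes from a VCF file
#'
#' Reads biallelic SNVs from a VCF (plain or bgzipped) into a
#' [genotype_matrix()]. Only the GT subfield is used. Genotypes are coded as
#' alt-allele counts; phased and unphased separators are treated identically,
#' and any call containing `.` (including half-calls like `0/.`) becomes
#' missing. Multiallelic records and non-SNV records (indels, symbolic
#' alleles) are skipped with a message giving the skipped count.
#'
#' @param path path to a VCF file with at least one sample and GT fields.
#' @return A [genotype_matrix()]; sample order follows the VCF header.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("cannot parse VCF ", path, ": ", conditionMessage(e))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)
  if (ncol(v@gt) < 2) stop("no samples in VCF: ", path)

  ref <- fix$REF
  alt <- fix$ALT
  snv <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snv)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip, " multiallelic/non-SNV record(s)")
  }
  if (!any(snv)) {
    stop("no usable biallelic SNV records in VCF: ", path,
         " (first record: ", fix$CHROM[1], ":", fix$POS[1], ")")
  }

  gt <- vcfR::extract.gt(v, element = "GT")[snv, , drop = FALSE]
  # strip phase, count alt alleles; anything with "." is missing
  code_gt <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    known <- !is.na(x) & !grepl("\\.", x)
    if (any(known)) {
      parts <- strsplit(x[known], "/", fixed = TRUE)
      out[known] <- vapply(parts, function(p) sum(as.integer(p)), integer(1))
    }
    out
  }
  calls <- t(matrix(code_gt(as.vector(gt)), nrow = nrow(gt)))  # samples x variants

  ids <- fix$ID[snv]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix$CHROM[snv][blank], ":", fix$POS[snv][blank])
  variants <- data.frame(
    variant_id = ids,
    chrom = fix$CHROM[snv],
    pos = as.integer(fix$POS[snv]),
    ref = ref[snv],
    alt = alt[snv],
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, variants, colnames(v@gt)[-1])
}

#' Read a genotype matrix from TSV
#'
#' Reads the package's plain-text genotype dialect: a main file whose header
#' row is `sample_id` followed by variant ids, one row per sample with cells
#' in {0, 1, 2, NA}; and a sidecar file `<path>.variants.tsv` (or
#' `<stem>.variants.tsv`) with columns
#' `variant_id, chrom, pos, ref, alt`.
#'
#' @param path path to the main genotype TSV.
#' @param variants_path optional explicit path to the variant sidecar;
#'   defaults to `<path without .tsv>.variants.tsv`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, variants_path = NULL) {
  if (!file.exists(path)) stop("genotype TSV not found: ", path)
  if (is.null(variants_path)) {
    variants_path <- paste0(sub("\\.tsv$", "", path), ".variants.tsv")
  }
  if (!file.exists(variants_path)) {
    stop("variant sidecar not found: ", variants_path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA")
  if (names(raw)[1] != "sample_id") {
    stop("genotype TSV must start with a sample_id column: ", path)
  }
  samples <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  ok <- is.na(cells) | cells %in% c("0", "1", "2")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid genotype cell '", cells[bad[1], bad[2]], "' at row ",
         bad[1], " (sample ", samples[bad[1]], "), column ", bad[2],
         " (", colnames(cells)[bad[2]], ")")
  }
  calls <- matrix(as.integer(cells), nrow = nrow(cells),
                  dimnames = dimnames(cells))

  variants <- utils::read.table(variants_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE,
                                colClasses = c("character", "character",
                                               "integer", "character",
                                               "character"))
  if (!identical(variants$variant_id, colnames(cells))) {
    stop("variant ids in sidecar do not match genotype TSV header: ",
         variants_path)
  }
  genotype_matrix(calls, variants, samples)
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_genotype_tsv()]: writes the main genotype file and the
#' `<stem>.variants.tsv` sidecar. Missing calls are written as `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path for the main file.
#' @return Invisibly, `path`.
#' @export
write_genotype_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  main <- data.frame(sample_id = g$samples, g$calls,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(main, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  sidecar <- paste0(sub("\\.tsv$", "", path), ".variants.tsv")
  utils::write.table(g$variants, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

valid_status <- c("case", "control")
valid_joint <- c("hip", "knee", "none")
valid_sex <- c("female", "male")
valid_yn <- c("yes", "no")

#' Read a sample metadata table
#'
#' Reads per-sample phenotype and covariate data: columns
#' `sample_id, status, joint, age, sex, bmi, diabetes`. `status` is
#' case/control; `joint` is hip/knee for cases and none for controls (blank
#' cells for controls are normalised to none). `age`, `sex`, `bmi`,
#' `diabetes` may be empty.
#'
#' @param path path to the sample TSV.
#' @return A validated data.frame (class `sample_table`).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  sample_table(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with columns `sample_id, status, joint, age, sex,
#'   bmi, diabetes` (the last four may hold NA).
#' @return The validated data.frame with class `sample_table` prepended and
#'   typed columns.
#' @export
sample_table <- function(df) {
  needed <- c("sample_id", "status", "joint", "age", "sex", "bmi", "diabetes")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("sample table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[needed]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  chk <- function(x, valid, name, allow_na = FALSE) {
    x <- as.character(x)
    bad <- !(x %in% valid) & !(allow_na & is.na(x))
    if (any(bad)) {
      stop("unknown ", name, " value '", x[which(bad)[1]], "' for sample ",
           df$sample_id[which(bad)[1]])
    }
    x
  }
  df$status <- chk(df$status, valid_status, "status")
  # blank joint for controls is normalised to "none"
  df$joint[is.na(df$joint) & df$status == "control"] <- "none"
  df$joint <- chk(df$joint, valid_joint, "joint")
  df$sex <- chk(df$sex, valid_sex, "sex", allow_na = TRUE)
  df$diabetes <- chk(df$diabetes, valid_yn, "diabetes", allow_na = TRUE)
  df$age <- as.numeric(df$age)
  df$bmi <- as.numeric(df$bmi)

  bad_joint <- (df$status == "control") != (df$joint == "none")
  if (any(bad_joint)) {
    stop("joint must be 'none' exactly for controls; offending sample: ",
         df$sample_id[which(bad_joint)[1]])
  }
  if (any(!is.na(df$age) & df$age <= 0)) stop("age must be positive")
  if (any(!is.na(df$bmi) & df$bmi <= 0)) stop("bmi must be positive")
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write a sample table to TSV
#'
#' @param samples a [sample_table()] data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a result table to TSV
#'
#' Writes heterozygosity profiles, association results or a QC report with a
#' fixed column order, floats at 6 significant digits and deterministic row
#' order (by `sample_id` then stratum for profiles; by stratum, metric,
#' subgroup for association results).
#'
#' @param rows a non-empty data.frame: a het-profile table, an association
#'   table, or a QC report (from [qc_report_table()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("refusing to write an empty table: ", path)
  if (all(c("sample_id", "stratum") %in% names(rows))) {
    rows <- rows[order(rows$sample_id, rows$stratum), ]
  } else if (all(c("stratum", "metric", "subgroup") %in% names(rows))) {
    rows <- rows[order(rows$stratum, rows$metric, rows$subgroup), ]
  }
  num <- vapply(rows, is.numeric, logical(1)) &
    !vapply(rows, is.integer, logical(1))
  rows[num] <- lapply(rows[num], signif, digits = 6)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
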