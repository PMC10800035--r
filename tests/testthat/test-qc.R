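test_that("allele_frequencies handles missingness and degenerate variants", {
  g <- make_gm(rbind(c(0L, 2L, 0L),
                     c(1L, 2L, 1L),
                     c(2L, 2L, NA)))
  fr <- allele_frequencies(g)
  expect_equal(fr$p_alt, c(0.5, 1.0, 0.25))
  expect_equal(fr$maf, c(0.5, 0.0, 0.25))
  expect_equal(fr$n_called, c(3L, 3L, 2L))

  g_all_na <- make_gm(matrix(NA_integer_, 2, 1))
  fr2 <- allele_frequencies(g_all_na)
  expect_true(is.na(fr2$p_alt))
})

test_that("MAF filter is strict and idempotent", {
  # frequencies chosen to land at 0.009, 0.05 and 0.30
  n <- 500
  calls <- cbind(c(rep(1L, 9), rep(0L, n - 9)),
                 c(rep(1L, 50), rep(0L, n - 50)),
                 c(rep(1L, 300), rep(0L, n - 300)))
  g <- make_gm(calls)
  fr <- allele_frequencies(g)
  expect_equal(fr$maf, c(0.009, 0.05, 0.30))

  r1 <- filter_maf(g, fr, maf_min = 0.01)
  expect_equal(r1$removed, "v001")           # 0.009 < 0.01 removed
  r2 <- filter_maf(g, fr, maf_min = 0.1)
  expect_equal(r2$removed, c("v001", "v002"))  # 0.05 removed at 0.1
  r0 <- filter_maf(g, fr, maf_min = 0)
  expect_equal(length(r0$removed), 0)        # only monomorphic would go

  again <- filter_maf(r1$genotypes, allele_frequencies(r1$genotypes), 0.01)
  expect_identical(again$genotypes$variants, r1$genotypes$variants)
  expect_error(filter_maf(g, fr, maf_min = 0.6), "maf_min")
})

test_that("missingness filter uses a strict threshold", {
  calls <- matrix(0L, 10, 3)
  calls[1, 2] <- NA          # rate 0.10
  calls[1:5, 3] <- NA        # rate 0.50
  g <- make_gm(calls)
  r <- filter_missingness(g, miss_max = 0.05)
  expect_equal(r$removed, c("v002", "v003"))
  # exactly at threshold: retained
  calls2 <- matrix(0L, 20, 1); calls2[1, 1] <- NA  # rate 0.05
  expect_equal(length(filter_missingness(make_gm(calls2), 0.05)$removed), 0)
  expect_equal(length(filter_missingness(g, 1)$removed), 0)
  expect_error(filter_missingness(g, -0.1), "miss_max")
})

test_that("HWE exact test equals the enumeration oracle exhaustively to n = 50", {
  for (n in c(1:12, 20, 35, 50)) {
    for (n_het in 0:n) {
      for (n_alt in 0:(n - n_het)) {
        n_ref <- n - n_het - n_alt
        expect_equal(hwe_exact_test(n_ref, n_het, n_alt),
                     hwe_oracle(n_ref, n_het, n_alt),
                     tolerance = 1e-9,
                     label = sprintf("triple (%d,%d,%d)", n_ref, n_het, n_alt))
      }
    }
  }
})

test_that("HWE exact test edge behaviour", {
  expect_lt(hwe_exact_test(0, 100, 0), 1e-20)  # extreme het excess
  expect_equal(hwe_exact_test(50, 0, 0), 1.0)  # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_error(hwe_exact_test(-1, 0, 5), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least 1")
  # vectorised
  expect_equal(hwe_exact_test(c(50, 0), c(0, 100), c(0, 0)),
               c(1.0, hwe_oracle(0, 100, 0)))
})

test_that("filter_hwe removes het-deficit variants and keeps HWE variants", {
  set.seed(7)
  p <- runif(30, 0.2, 0.5)
  g_bad <- simulate_genotypes(p, rep(0.8, 500), seed = 21)
  r <- filter_hwe(g_bad, hwe_alpha = 1e-6)
  expect_gte(length(r$removed), 29)  # power ~1 at F = 0.8, n = 500

  g_ok <- simulate_genotypes(p, rep(0, 500), seed = 22)
  r2 <- filter_hwe(g_ok, hwe_alpha = 1e-6)
  expect_equal(length(r2$removed), 0)
  expect_error(filter_hwe(g_ok, hwe_alpha = 0), "hwe_alpha")
})

test_that("HWE removal rate under the null approximates alpha", {
  # exact conditional test is discrete, hence conservative: rate <= ~alpha
  set.seed(33)
  p <- runif(2000, 0.1, 0.5)
  g <- simulate_genotypes(p, rep(0, 300), seed = 34)
  alpha <- 0.05
  r <- filter_hwe(g, hwe_alpha = alpha)
  rate <- length(r$removed) / 2000
  se <- sqrt(alpha * (1 - alpha) / 2000)
  expect_lte(rate, alpha + 3 * se)
  expect_gte(rate, 0.005)  # rejects at a nontrivial rate
})

test_that("find_duplicates reports exact copies and not independent samples", {
  g <- random_gm(12, 1000, miss = 0.02, seed = 5)
  calls <- rbind(g$calls, g$calls[3, ])
  gd <- make_gm(calls)
  dup <- find_duplicates(gd, ibs_min = 0.95)
  expect_equal(nrow(dup), 1)
  expect_equal(sort(c(dup$sample_1, dup$sample_2)), c("S003", "S013"))
  expect_equal(dup$ibs, 1.0)

  none <- find_duplicates(g, ibs_min = 0.95)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(find_duplicates(make_gm(matrix(0L, 1, 10)))), 0)
})

test_that("find_duplicates skips pairs with too little overlap", {
  calls <- matrix(NA_integer_, 3, 60)
  calls[1, 1:60] <- 0L
  calls[2, 1:30] <- 0L   # only 30 overlapping with S1, identical there
  calls[3, 1:60] <- 0L
  g <- make_gm(calls)
  expect_warning(dup <- find_duplicates(g, ibs_min = 0.95), "50 overlapping")
  expect_false(any(dup$sample_1 == "S002" | dup$sample_2 == "S002"))
})

test_that("check_sex flags discordant samples from X heterozygosity", {
  set.seed(8)
  n <- 40
  m <- 200
  sex <- rep(c("female", "male"), each = n / 2)
  xcalls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    pj <- runif(1, 0.2, 0.5)
    u <- runif(n)
    het <- 2 * pj * (1 - pj)
    xcalls[, j] <- ifelse(sex == "male",
                          ifelse(u < pj, 2L, 0L),
                          ifelse(u < het, 1L, ifelse(u < het + pj^2, 2L, 0L)))
  }
  g <- make_gm(xcalls, chrom = rep("X", m))
  s <- make_samples(20, 20, seed = 8)
  s$sex <- sex
  expect_equal(check_sex(g, s), character())

  # swap two recorded sexes
  s$sex[1] <- "male"    # truly female: X het ~0.35 > 0.10
  s$sex[n] <- "female"  # truly male: X het 0 < 0.05
  expect_equal(sort(check_sex(g, s)), sort(c(s$sample_id[1], s$sample_id[n])))

  g_auto <- make_gm(xcalls, chrom = rep("1", m))
  expect_warning(res <- check_sex(g_auto, s), "no X")
  expect_equal(res, character())
})

test_that("run_qc applies all filters with exact accounting", {
  cfg <- sim_config(n_samples = 250, n_snps = 600, n_x_snps = 100,
                    n_hwe_violations = 10, n_duplicates = 1, n_sex_swaps = 2,
                    missing_rate = 0.01, seed = 77)
  co <- generate_cohort(cfg)
  res <- suppressWarnings(run_qc(co$genotypes, co$samples))
  rep <- res$report

  expect_equal(rep$removed_duplicate_samples, 1)
  expect_equal(rep$removed_sex_discordant, 2)
  expect_equal(rep$removed_by_hwe, 10)
  expect_setequal(rep$removed_variant_ids$hwe, co$truth$hwe_variants)
  expect_true(all(unlist(
    rep$removed_sample_ids$sex_discordant) %in% co$truth$sex_swapped))

  # accounting identities (variant filters act on autosomes)
  n_auto_in <- sum(co$genotypes$variants$chrom %in% as.character(1:22))
  n_auto_out <- sum(res$genotypes$variants$chrom %in% as.character(1:22))
  expect_equal(n_auto_out,
               n_auto_in - rep$removed_by_missingness - rep$removed_by_hwe -
                 rep$removed_by_maf)
  expect_equal(rep$n_samples_out,
               rep$n_samples_in - rep$removed_duplicate_samples -
                 rep$removed_sex_discordant - rep$removed_excluded_samples)
  # thresholds echoed
  expect_equal(rep$thresholds$maf_min, 0.01)
  expect_equal(rep$thresholds$miss_max, 0.05)
})

test_that("run_qc leaves a clean cohort untouched", {
  cfg <- sim_config(n_samples = 200, n_snps = 400, n_x_snps = 80, seed = 5)
  co <- generate_cohort(cfg)
  res <- run_qc(co$genotypes, co$samples)
  rep <- res$report
  expect_equal(rep$removed_duplicate_samples +
                 rep$removed_sex_discordant + rep$removed_by_missingness +
                 rep$removed_by_hwe + rep$removed_by_maf, 0)
  expect_identical(res$genotypes$calls, co$genotypes$calls)
})

test_that("filter order does not change the final set for independent violations", {
  n <- 400
  set.seed(12)
  g_base <- simulate_genotypes(runif(20, 0.2, 0.5), rep(0, n), seed = 13)
  calls <- g_base$calls
  calls[seq_len(0.2 * n), 1] <- NA                      # missingness violation
  calls[, 2] <- rep(c(0L, 2L), length.out = n)          # extreme HWE violation
  calls[, 3] <- c(1L, rep(0L, n - 1))                   # rare: MAF violation
  g <- make_gm(calls)

  orders <- list(
    c("miss", "hwe", "maf"), c("maf", "hwe", "miss"), c("hwe", "miss", "maf"))
  final <- lapply(orders, function(ord) {
    gg <- g
    for (step in ord) {
      gg <- switch(step,
        miss = filter_missingness(gg, 0.05)$genotypes,
        hwe = filter_hwe(gg, 1e-6)$genotypes,
        maf = filter_maf(gg, allele_frequencies(gg), 0.01)$genotypes)
    }
    gg$variants$variant_id
  })
  expect_equal(final[[1]], final[[2]])
  expect_equal(final[[1]], final[[3]])
  expect_false(any(c("v001", "v002", "v003") %in% final[[1]]))
})

test_that("run_qc hard-errors when everything is removed", {
  g <- make_gm(matrix(c(1L, rep(0L, 99)), 100, 1))  # MAF 0.005 variant only
  s <- make_samples(50, 50)
  expect_error(suppressWarnings(run_qc(g, s)), "QC removed everything")
})
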