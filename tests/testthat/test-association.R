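test_that("fit_logistic matches a grid-search likelihood maximizer on small fixtures", {
  fixtures <- list(
    list(y = c(0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1),
         x = c(-1.2, -0.8, -0.5, -0.4, -0.1, 0.0, 0.2, 0.4, 0.6, 0.9, 0.3, 1.4)),
    list(y = c(1, 0, 0, 1, 1, 0, 0, 1, 0, 1),
         x = c(2.1, -0.3, 1.1, 0.7, -0.9, 0.2, 1.4, 0.4, -1.6, -0.5)),
    list(y = c(0, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 0, 0),
         x = c(0.1, 0.5, -0.7, 1.2, 0.8, -1.4, 0.3, 1.9, -0.2, -0.6,
               0.9, -1.1, 0.4, 1.5, 0.0))
  )
  for (fx in fixtures) {
    fit <- fit_logistic(fx$y, cbind(1, z = fx$x))
    oracle <- grid_logistic(fx$y, fx$x)
    expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-3)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
    expect_true(fit$converged)
  }
})

test_that("fit_logistic null behaviour, separation flag, and input checks", {
  set.seed(101)
  x <- rnorm(500)
  y <- rbinom(500, 1, 0.5)
  fit <- fit_logistic(y, cbind(1, z = x))
  expect_lt(abs(fit$beta[["z"]]), 3 * fit$se[["z"]] + 0.3)

  # perfectly separated toy data
  ys <- c(0, 0, 0, 1, 1, 1)
  xs <- c(-3, -2, -1, 1, 2, 3)
  fit_sep <- fit_logistic(ys, cbind(1, z = xs))
  expect_false(fit_sep$converged)

  expect_error(fit_logistic(rep(1, 10), cbind(1, z = rnorm(10))),
               "both classes")
  expect_error(fit_logistic(y, cbind(1, z = x, bad = 2)), "constant")
  expect_message(fit_logistic(c(y, NA), rbind(cbind(1, z = x), c(1, 0))),
                 "dropped 1")
})

test_that("fit_logistic agrees with glm() including Wald SEs", {
  set.seed(102)
  x1 <- rnorm(200); x2 <- rbinom(200, 1, 0.4)
  y <- rbinom(200, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  fit <- fit_logistic(y, cbind("(Intercept)" = 1, x1 = x1, x2 = x2))
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-5)
})

test_that("association_test recovers a simulated protective per-SD odds ratio", {
  cfg <- sim_config(n_samples = 800, case_fraction = 0.5, n_snps = 8000,
                    n_x_snps = 0, beta_het = log(0.6),
                    f_dist = list(law = "normal_truncated",
                                  mean = 0.05, sd = 0.03),
                    cov_f_age = 0, cov_f_bmi = 0, seed = 111)
  co <- generate_cohort(cfg)
  prof <- compute_het_profiles(co$genotypes, 0.01)
  res <- association_test(prof, co$samples, "het_excess", "all_oa")
  expect_lt(abs(res$or_per_sd - 0.6), 0.15)
  expect_true(res$converged)
  expect_lt(res$p, 0.05)
  # shared analysis set across metrics
  res_hr <- association_test(prof, co$samples, "het_rate", "all_oa")
  expect_equal(res_hr$n_case + res_hr$n_control,
               res$n_case + res$n_control)
})

test_that("association result satisfies its internal identities", {
  cfg <- sim_config(n_samples = 300, n_snps = 1500, n_x_snps = 0, seed = 121)
  co <- generate_cohort(cfg)
  prof <- compute_het_profiles(co$genotypes, 0.01)
  res <- association_test(prof, co$samples, "het_rate", "all_oa",
                          covariates = c("age", "sex", "bmi"))
  expect_equal(res$or_per_sd, exp(res$beta))
  expect_equal(res$ci_low, exp(res$beta - 1.96 * res$se))
  expect_equal(res$ci_high, exp(res$beta + 1.96 * res$se))
  expect_true(res$ci_low < res$or_per_sd & res$or_per_sd < res$ci_high)
  expect_true(res$p > 0 & res$p <= 1)
  expect_equal(res$covariates, "age,sex,bmi")
  # diabetes-adjusted model also fits
  res_d <- association_test(prof, co$samples, "het_rate", "all_oa",
                            covariates = c("age", "sex", "bmi", "diabetes"))
  expect_true(is.finite(res_d$beta))
  expect_error(association_test(prof, co$samples, "het_rate", "all_oa",
                                covariates = "smoking"), "unknown covariate")
})

test_that("subgroups keep the full control set against each case subset", {
  cfg <- sim_config(n_samples = 400, n_snps = 1000, n_x_snps = 0, seed = 131)
  co <- generate_cohort(cfg)
  prof <- compute_het_profiles(co$genotypes, 0.01)
  all_res <- association_test(prof, co$samples, "het_excess", "all_oa")
  hip <- association_test(prof, co$samples, "het_excess", "hip")
  knee <- association_test(prof, co$samples, "het_excess", "knee")
  expect_equal(hip$n_control, all_res$n_control)
  expect_equal(knee$n_control, all_res$n_control)
  expect_equal(hip$n_case + knee$n_case, all_res$n_case)
})

test_that("analysis_grid produces the 12-cell grid with protective ORs", {
  cfg <- sim_config(n_samples = 600, case_fraction = 0.5, n_snps = 6000,
                    n_x_snps = 0, beta_het = log(0.4),
                    f_dist = list(law = "normal_truncated",
                                  mean = 0.08, sd = 0.04),
                    cov_f_age = 0, cov_f_bmi = 0, seed = 141)
  co <- generate_cohort(cfg)
  freqs <- allele_frequencies(co$genotypes)
  profs <- list(
    maf_gt_001 = compute_het_profiles(co$genotypes, 0.01, freqs = freqs),
    maf_gt_01 = compute_het_profiles(co$genotypes, 0.1, freqs = freqs))
  grid <- analysis_grid(profs, co$samples)
  expect_equal(nrow(grid), 12)
  expect_equal(sort(unique(grid$metric)), c("het_excess", "het_rate"))
  expect_equal(sort(unique(grid$subgroup)), c("all_oa", "hip", "knee"))
  expect_true(all(grid$or_per_sd < 1))
})

test_that("type-I error of the association test is at the nominal level", {
  # null: heterozygosity independent of status
  set.seed(151)
  n_rep <- 400
  p_vals <- vapply(seq_len(n_rep), function(r) {
    n <- 200
    f <- pmax(rnorm(n, 0.03, 0.02), 0)
    z <- zscore(-f + rnorm(n, 0, 0.01))
    status <- rbinom(n, 1, 0.5)
    prof <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       stratum = "maf_gt_001",
                       z_het_rate = z, z_het_excess = z)
    samples <- sample_table(data.frame(
      sample_id = prof$sample_id,
      status = ifelse(status == 1, "case", "control"),
      joint = ifelse(status == 1, "knee", "none"),
      age = rnorm(n, 60, 8), sex = "female", bmi = rnorm(n, 30, 5),
      diabetes = "no", stringsAsFactors = FALSE))
    association_test(prof, samples, "het_excess", "all_oa")$p
  }, numeric(1))
  rej <- mean(p_vals < 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej - 0.05), 3 * se)
})

test_that("pearson_corr matches the direct formula and handles edge input", {
  expect_equal(pearson_corr(1:10, 2 * (1:10))$r, 1.0)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1.0)
  set.seed(161)
  x <- rnorm(10); y <- rnorm(10)
  pc <- pearson_corr(x, y)
  r_direct <- cov(x, y) / sqrt(var(x) * var(y))
  expect_equal(pc$r, r_direct, tolerance = 1e-12)
  t_stat <- r_direct * sqrt(8 / (1 - r_direct^2))
  expect_equal(pc$p, 2 * pt(-abs(t_stat), df = 8), tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_corr(1:2, 1:2), "3 complete pairs")
})

test_that("students_ttest matches the pooled-variance formula", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  tt <- students_ttest(x, y)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 4)

  same <- students_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  swapped <- students_ttest(y, x)
  expect_equal(swapped$t, -tt$t)
  expect_equal(swapped$p, tt$p)
  expect_error(students_ttest(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("proportion_test is the uncorrected chi-square on the 2x2 table", {
  expect_equal(proportion_test(10, 20, 10, 20)$p, 1.0)
  ext <- proportion_test(20, 20, 0, 20)
  expect_equal(ext$chisq, 40)  # hand-computed: n * (ad - bc)^2 / row/col prods
  expect_lt(ext$p, 1e-6)
  a <- proportion_test(5, 30, 9, 25)
  b <- proportion_test(9, 25, 5, 30)
  expect_equal(a$p, b$p)
  expect_warning(proportion_test(1, 40, 0, 2), "below 1")
  expect_error(proportion_test(5, 4, 1, 10), "0 <= k <= n")
})

test_that("cohort_summary reproduces direct computations on a small fixture", {
  s <- sample_table(data.frame(
    sample_id = paste0("S", 1:6),
    status = c("case", "case", "case", "case", "control", "control"),
    joint = c("hip", "hip", "knee", "knee", "none", "none"),
    age = c(70, 64, 66, 68, 55, 57),
    sex = c("female", "female", "male", "female", "female", "male"),
    bmi = c(33, 35, 31, 37, 29, 30),
    diabetes = "no", stringsAsFactors = FALSE))
  cs <- suppressWarnings(cohort_summary(s))  # tiny groups: expected cells < 1
  case_row <- cs$groups[cs$groups$group == "case", ]
  expect_equal(case_row$n, 4)
  expect_equal(case_row$mean_age, mean(c(70, 64, 66, 68)))
  expect_equal(case_row$sd_age, sd(c(70, 64, 66, 68)))
  expect_equal(case_row$pct_female, 75)
  expect_equal(cs$groups$n[cs$groups$group == "hip"] +
                 cs$groups$n[cs$groups$group == "knee"], 4)
  expect_equal(cs$tests$p_age[1], students_ttest(c(70, 64, 66, 68),
                                                 c(55, 57))$p)

  # identical groups: all comparisons null
  s2 <- sample_table(data.frame(
    sample_id = paste0("T", 1:8),
    status = rep(c("case", "control"), each = 4),
    joint = rep(c("knee", "none"), each = 4),
    age = rep(c(60, 62, 64, 66), 2),
    sex = rep(c("female", "male", "female", "male"), 2),
    bmi = rep(c(30, 31, 32, 33), 2),
    diabetes = "no", stringsAsFactors = FALSE))
  cs2 <- cohort_summary(s2)
  expect_equal(cs2$tests$p_age[1], 1)
  expect_equal(cs2$tests$p_bmi[1], 1)
  expect_equal(cs2$tests$p_sex[1], 1)
})
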