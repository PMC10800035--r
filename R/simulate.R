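#' Simulation configuration
#'
#' Parameters of the synthetic case-control cohort generator. The defaults
#' describe a desk-scale cohort shaped like an end-stage osteoarthritis
#' case-control study: ~83% cases, hip:knee roughly 1:2.25, covariate means
#' and spreads at the magnitudes of such cohorts (age ~ N(62, 9^2) years,
#' BMI ~ N(32, 6^2) kg/m^2, 56% female, 15% diabetes), weak inbreeding
#' variation (F ~ truncated N(0.01, 0.01^2)), a protective per-SD
#' heterozygosity effect of log(0.65), and small covariate-heterozygosity
#' correlations (about -0.09 with age, +0.09 with BMI).
#'
#' @param n_samples cohort size (before duplicate injection).
#' @param case_fraction target case fraction; ignored when `n_cases` is set.
#' @param n_cases optional exact case count (takes precedence).
#' @param hip_fraction_of_cases probability a case is hip rather than knee.
#' @param n_snps autosomal SNP count.
#' @param n_x_snps X-chromosome SNP count (sex-aware, for the sex check).
#' @param maf_dist list: `law` "uniform" (`min`, `max` within (0, 0.5]) or
#'   "beta" (`shape1`, `shape2` > 0; draws folded into (0, 0.5]).
#' @param f_dist list: `law` "point" (`value`), "normal_truncated" (`mean`,
#'   `sd`; truncated to (-0.2, 1)) or "beta" (`shape1`, `shape2`).
#' @param beta_het per-SD log-odds of the heterozygosity propensity
#'   s = z(-F); negative values make heterozygosity protective.
#' @param beta_age,beta_sex,beta_bmi,beta_diabetes covariate log-odds (age
#'   and BMI enter mean-centered; sex coded male = 1; diabetes yes = 1).
#' @param cov_f_age,cov_f_bmi target Pearson correlation of age/BMI with
#'   the heterozygosity propensity -F, each in (-1, 1).
#' @param pct_female,pct_diabetes Bernoulli rates for sex and diabetes.
#' @param missing_rate per-call missingness probability.
#' @param n_hwe_violations,n_duplicates,n_sex_swaps injected QC violations.
#' @param seed integer master seed; every draw flows from named substreams
#'   of it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 677,
                       case_fraction = 559 / 677,
                       n_cases = NULL,
                       hip_fraction_of_cases = 172 / 559,
                       n_snps = 5000,
                       n_x_snps = 150,
                       maf_dist = list(law = "uniform", min = 0.05, max = 0.5),
                       f_dist = list(law = "normal_truncated",
                                     mean = 0.01, sd = 0.01),
                       beta_het = log(0.65),
                       beta_age = 0, beta_sex = 0, beta_bmi = 0,
                       beta_diabetes = 0,
                       cov_f_age = -0.089, cov_f_bmi = 0.091,
                       pct_female = 0.56, pct_diabetes = 0.15,
                       missing_rate = 0,
                       n_hwe_violations = 0, n_duplicates = 0,
                       n_sex_swaps = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_samples >= 2, n_snps >= 1,
            case_fraction >= 0, case_fraction <= 1,
            hip_fraction_of_cases >= 0, hip_fraction_of_cases <= 1,
            missing_rate >= 0, missing_rate < 1,
            abs(cov_f_age) < 1, abs(cov_f_bmi) < 1)
  class(cfg) <- "sim_config"
  cfg
}

# independent named substreams derived from one master seed (kept < 2^31)
substream_seed <- function(seed, stream) {
  streams <- c(freqs = 1L, f = 2L, genotypes = 3L, covariates = 4L,
               outcome = 5L, artifacts = 6L, x_block = 7L)
  if (!stream %in% names(streams)) stop("unknown substream: ", stream)
  (as.integer(seed) %% 1000003L) * 2011L + streams[[stream]] * 7919L
}

#' Draw variant allele frequencies
#'
#' Minor-allele frequencies for the simulated variants; the alt allele is
#' the minor allele by construction, so every draw lies in (0, 0.5].
#'
#' @param n_snps number of variants.
#' @param maf_dist distribution spec, see [sim_config()].
#' @param seed integer seed.
#' @return numeric vector of length `n_snps`.
#' @export
draw_allele_freqs <- function(n_snps,
                              maf_dist = list(law = "uniform",
                                              min = 0.05, max = 0.5),
                              seed = 1L) {
  stopifnot(n_snps >= 1)
  set.seed(seed)
  p <- switch(maf_dist$law,
    uniform = {
      if (!(maf_dist$min > 0 && maf_dist$max <= 0.5 &&
            maf_dist$min < maf_dist$max)) {
        stop("uniform maf_dist bounds must satisfy 0 < min < max <= 0.5")
      }
      stats::runif(n_snps, maf_dist$min, maf_dist$max)
    },
    beta = {
      if (!(maf_dist$shape1 > 0 && maf_dist$shape2 > 0)) {
        stop("beta maf_dist shapes must be positive")
      }
      x <- stats::rbeta(n_snps, maf_dist$shape1, maf_dist$shape2)
      pmax(pmin(x, 1 - x), 1e-4)  # fold onto the minor allele
    },
    stop("unknown maf_dist law: ", maf_dist$law)
  )
  p
}

# per-sample inbreeding coefficients
draw_f <- function(n, f_dist, seed) {
  set.seed(seed)
  switch(f_dist$law,
    point = rep(f_dist$value, n),
    normal_truncated = {
      x <- stats::rnorm(n, f_dist$mean, f_dist$sd)
      pmin(pmax(x, -0.2), 0.999)
    },
    beta = stats::rbeta(n, f_dist$shape1, f_dist$shape2),
    stop("unknown f_dist law: ", f_dist$law)
  )
}

#' Simulate genotypes under per-individual inbreeding
#'
#' Independent draws per sample x variant from the inbreeding model
#' P(het) = 2p(1-p)(1-F), P(hom alt) = p^2 + F p(1-p),
#' P(hom ref) = (1-p)^2 + F p(1-p), under which the expected observed
#' heterozygosity is (1-F) times the Hardy-Weinberg expectation. Negative F
#' is clamped per variant to the largest value keeping all three
#' probabilities non-negative. Chromosome labels 1-22 are assigned
#' round-robin.
#'
#' @param p alt (minor) allele frequency per variant, in (0, 1).
#' @param f per-sample inbreeding coefficient.
#' @param seed integer seed.
#' @param id_prefix prefix for variant and sample ids.
#' @return a [genotype_matrix()] of `length(f)` samples x `length(p)`
#'   variants.
#' @export
simulate_genotypes <- function(p, f, seed = 1L, id_prefix = "snp") {
  if (length(p) == 0 || length(f) == 0) stop("empty p or f")
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must be in (0, 1)")
  set.seed(seed)
  m <- length(p)
  n <- length(f)
  f_floor <- -pmin(p / (1 - p), (1 - p) / p)  # validity bound per variant
  calls <- matrix(NA_integer_, n, m)
  pq <- p * (1 - p)
  for (i in seq_len(n)) {
    fe <- pmax(f[i], f_floor)
    p_het <- 2 * pq * (1 - fe)
    p_alt <- p^2 + fe * pq
    u <- stats::runif(m)
    calls[i, ] <- ifelse(u < p_het, 1L, ifelse(u < p_het + p_alt, 2L, 0L))
  }
  variants <- data.frame(
    variant_id = sprintf("%s%06d", id_prefix, seq_len(m)),
    chrom = as.character(rep_len(1:22, m)),
    pos = seq_len(m) * 1000L,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, variants, sprintf("S%05d", seq_len(n)))
}

# z-standardize, tolerating a constant vector (returns zeros)
safe_z <- function(x) {
  if (stats::sd(x) == 0) return(rep(0, length(x)))
  zscore(x)
}

#' Simulate covariates with controlled correlation to heterozygosity
#'
#' Age and BMI are bivariate-normal constructions with the requested
#' Pearson correlation against the heterozygosity propensity -F; sex and
#' diabetes are independent Bernoulli draws.
#'
#' @param n number of samples (must match `length(f)`).
#' @param cov_f_age,cov_f_bmi target correlations with -F, each in (-1, 1).
#' @param f per-sample inbreeding coefficients.
#' @param seed integer seed.
#' @param pct_female,pct_diabetes Bernoulli rates.
#' @return data.frame with columns `age`, `sex`, `bmi`, `diabetes`.
#' @export
simulate_covariates <- function(n, cov_f_age = 0, cov_f_bmi = 0, f,
                                seed = 1L, pct_female = 0.56,
                                pct_diabetes = 0.15) {
  if (abs(cov_f_age) >= 1 || abs(cov_f_bmi) >= 1) {
    stop("correlations must lie in (-1, 1)")
  }
  stopifnot(n == length(f))
  set.seed(seed)
  z_het <- safe_z(-f)
  mix <- function(rho, mu, sd) {
    e <- stats::rnorm(n)
    mu + sd * (rho * z_het + sqrt(1 - rho^2) * e)
  }
  data.frame(
    age = mix(cov_f_age, 62, 9),
    sex = ifelse(stats::runif(n) < pct_female, "female", "male"),
    bmi = mix(cov_f_bmi, 32, 6),
    diabetes = ifelse(stats::runif(n) < pct_diabetes, "yes", "no"),
    stringsAsFactors = FALSE
  )
}

#' Simulate disease status from the logistic model
#'
#' Case status follows P(case) = logistic(beta0 + beta_het * s + covariate
#' terms) with s = z(-F) the standardized heterozygosity propensity and age
#' and BMI mean-centered. The intercept beta0 is tuned against the realized
#' uniform draws (a monotone step function of beta0) so the realized case
#' count hits the target exactly. Cases are assigned the hip joint with
#' probability `hip_fraction_of_cases`, knee otherwise.
#'
#' @param f per-sample inbreeding coefficients.
#' @param covariates data.frame from [simulate_covariates()].
#' @param config a [sim_config()].
#' @return list with `status` ("case"/"control"), `joint`
#'   ("hip"/"knee"/"none"), `beta0` (tuned intercept), `s` (propensity).
#' @export
simulate_outcome <- function(f, covariates, config) {
  n <- length(f)
  stopifnot(nrow(covariates) == n)
  s <- safe_z(-f)
  lin <- config$beta_het * s +
    config$beta_age * (covariates$age - mean(covariates$age)) +
    config$beta_sex * (covariates$sex == "male") +
    config$beta_bmi * (covariates$bmi - mean(covariates$bmi)) +
    config$beta_diabetes * (covariates$diabetes == "yes")
  if (any(!is.finite(lin))) stop("non-finite linear predictor")

  k <- if (!is.null(config$n_cases)) {
    as.integer(config$n_cases)
  } else {
    as.integer(round(config$case_fraction * n))
  }
  if (k < 1 || k > n - 1) {
    stop("target case count ", k, " leaves an empty group (n = ", n, ")")
  }
  set.seed(substream_seed(config$seed, "outcome"))
  u <- stats::runif(n)
  # sample i becomes a case iff beta0 exceeds t_i = logit(u_i) - lin_i
  t_crit <- stats::qlogis(u) - lin
  ts <- sort(t_crit)
  beta0 <- (ts[k] + ts[k + 1]) / 2
  status <- ifelse(t_crit < beta0, "case", "control")
  joint <- rep("none", n)
  idx <- which(status == "case")
  joint[idx] <- ifelse(stats::runif(length(idx)) < config$hip_fraction_of_cases,
                       "hip", "knee")
  list(status = status, joint = joint, beta0 = beta0, s = s)
}

#' Inject QC violations and the sex-aware X block
#'
#' Adds, in order: random missingness at `missing_rate`; replacement of
#' `n_hwe_violations` randomly chosen autosomal variants with
#' strong-heterozygote-deficit genotypes (F = 0.8 at that variant for every
#' sample); a sex-aware X-chromosome block (`n_x_snps` variants; males
#' hemizygous, hence no heterozygotes; females under HWE); `n_sex_swaps`
#' recorded-sex swaps; and `n_duplicates` exact sample copies appended
#' under new ids. All injections are recorded in the returned truth
#' registry.
#'
#' @param g autosomal [genotype_matrix()] from [simulate_genotypes()].
#' @param samples a [sample_table()] for `g`.
#' @param config a [sim_config()].
#' @return list with `genotypes`, `samples`, and `truth` (list with
#'   registries `hwe_variants`, `duplicate_pairs`, `sex_swapped`).
#' @export
inject_artifacts <- function(g, samples, config) {
  set.seed(substream_seed(config$seed, "artifacts"))
  n <- length(g$samples)
  if (config$n_hwe_violations > nrow(g$variants)) {
    stop("n_hwe_violations exceeds available variants")
  }
  if (config$n_duplicates > n) stop("n_duplicates exceeds available samples")
  if (config$n_sex_swaps > n) stop("n_sex_swaps exceeds available samples")

  calls <- g$calls
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow(calls), ncol(calls))
    calls[mask] <- NA_integer_
  }

  hwe_ids <- character()
  if (config$n_hwe_violations > 0) {
    vi <- sample.int(ncol(calls), config$n_hwe_violations)
    hwe_ids <- g$variants$variant_id[vi]
    freqs <- allele_frequencies(g)
    for (j in vi) {
      pj <- max(min(freqs$p_alt[j], 0.95), 0.05)
      gj <- simulate_genotypes(pj, rep(0.8, n),
                               seed = substream_seed(config$seed, "artifacts") +
                                 j %% 1000L)
      keep_na <- is.na(calls[, j])
      calls[, j] <- gj$calls[, 1]
      calls[keep_na, j] <- NA_integer_
    }
  }
  g2 <- genotype_matrix(calls, g$variants, g$samples)

  # sex-aware X block generated from the true (pre-swap) sex
  if (config$n_x_snps > 0) {
    set.seed(substream_seed(config$seed, "x_block"))
    px <- draw_allele_freqs(config$n_x_snps, config$maf_dist,
                            seed = substream_seed(config$seed, "x_block"))
    male <- samples$sex == "male"
    xcalls <- matrix(NA_integer_, n, config$n_x_snps)
    for (j in seq_len(config$n_x_snps)) {
      pj <- px[j]
      u <- stats::runif(n)
      het <- 2 * pj * (1 - pj)
      xcalls[, j] <- ifelse(male,
                            ifelse(u < pj, 2L, 0L),
                            ifelse(u < het, 1L,
                                   ifelse(u < het + pj^2, 2L, 0L)))
    }
    if (config$missing_rate > 0) {
      xmask <- matrix(stats::runif(length(xcalls)) < config$missing_rate,
                      n, config$n_x_snps)
      xcalls[xmask] <- NA_integer_
    }
    xvars <- data.frame(
      variant_id = sprintf("xsnp%05d", seq_len(config$n_x_snps)),
      chrom = "X",
      pos = seq_len(config$n_x_snps) * 1000L,
      ref = "A", alt = "G", stringsAsFactors = FALSE
    )
    g2 <- genotype_matrix(cbind(g2$calls, xcalls),
                          rbind(g2$variants, xvars), g2$samples)
  }

  s2 <- as.data.frame(samples)
  swapped <- character()
  if (config$n_sex_swaps > 0) {
    si <- sample.int(n, config$n_sex_swaps)
    swapped <- s2$sample_id[si]
    s2$sex[si] <- ifelse(s2$sex[si] == "male", "female", "male")
  }

  dup_pairs <- NULL
  if (config$n_duplicates > 0) {
    di <- sample.int(n, config$n_duplicates)
    new_ids <- paste0(s2$sample_id[di], "_dup")
    dup_calls <- g2$calls[di, , drop = FALSE]
    g2 <- genotype_matrix(rbind(g2$calls, dup_calls), g2$variants,
                          c(g2$samples, new_ids))
    dup_rows <- s2[di, , drop = FALSE]
    dup_rows$sample_id <- new_ids
    s2 <- rbind(s2, dup_rows)
    dup_pairs <- data.frame(original = samples$sample_id[di],
                            copy = new_ids, stringsAsFactors = FALSE)
  }

  list(genotypes = g2, samples = sample_table(s2),
       truth = list(hwe_variants = hwe_ids,
                    duplicate_pairs = dup_pairs,
                    sex_swapped = swapped))
}

#' Generate a complete synthetic cohort
#'
#' Composes allele-frequency draws, per-sample inbreeding, genotype
#' simulation, covariates, the logistic outcome and artifact injection into
#' one reproducible cohort with its ground truth.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `samples` (a
#'   [sample_table()]), and `truth` (per-sample `f`, propensity `s`, the
#'   tuned intercept `beta0`, `beta_het`, injection registries, `seed`).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  p <- draw_allele_freqs(config$n_snps, config$maf_dist,
                         seed = substream_seed(config$seed, "freqs"))
  f <- draw_f(config$n_samples, config$f_dist,
              seed = substream_seed(config$seed, "f"))
  g <- simulate_genotypes(p, f, seed = substream_seed(config$seed, "genotypes"))
  cov <- simulate_covariates(config$n_samples, config$cov_f_age,
                             config$cov_f_bmi, f,
                             seed = substream_seed(config$seed, "covariates"),
                             pct_female = config$pct_female,
                             pct_diabetes = config$pct_diabetes)
  out <- simulate_outcome(f, cov, config)
  samples <- sample_table(data.frame(
    sample_id = g$samples, status = out$status, joint = out$joint,
    age = cov$age, sex = cov$sex, bmi = cov$bmi, diabetes = cov$diabetes,
    stringsAsFactors = FALSE
  ))
  inj <- inject_artifacts(g, samples, config)
  truth <- c(list(f = f, s = out$s, beta0 = out$beta0,
                  beta_het = config$beta_het, seed = config$seed),
             inj$truth)
  list(genotypes = inj$genotypes, samples = inj$samples, truth = truth)
}
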