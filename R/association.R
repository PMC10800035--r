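#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around base R's iteratively reweighted least squares
#' (`glm.fit`, binomial family, logit link) returning coefficients, Wald
#' standard errors from the information matrix at the optimum, the
#' log-likelihood, and a convergence flag. Complete separation (a monotone
#' likelihood driving coefficients to infinity) is detected and reported as
#' `converged = FALSE` rather than raising an error.
#'
#' @param outcome binary 0/1 vector containing both classes.
#' @param design numeric design matrix including the intercept column; no
#'   non-intercept column may be constant. Rows with any missing value in
#'   `outcome` or `design` are dropped listwise with a message.
#' @return list with `beta`, `se` (named vectors), `loglik`, `converged`,
#'   `n` (rows used), `n_dropped`.
#' @export
fit_logistic <- function(outcome, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- c("(Intercept)",
                          paste0("x", seq_len(ncol(design) - 1)))[seq_len(ncol(design))]
  }
  cc <- stats::complete.cases(outcome, design)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message("fit_logistic: dropped ", n_dropped, " row(s) with missing values")
  }
  y <- outcome[cc]
  X <- design[cc, , drop = FALSE]
  if (length(unique(y)) < 2) {
    stop("outcome must contain both classes")
  }
  is_const <- apply(X, 2, function(col) length(unique(col)) == 1)
  is_intercept <- apply(X, 2, function(col) all(col == 1))
  if (any(is_const & !is_intercept)) {
    stop("constant non-intercept column in design: ",
         paste(colnames(X)[is_const & !is_intercept], collapse = ", "))
  }

  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  # separation: fitted probabilities pinned at 0/1 with diverging slopes
  eps <- 1e-8
  separated <- any(abs(beta) > 15) && all(mu < eps | mu > 1 - eps)
  converged <- fit$converged && !separated

  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e)
    rep(NA_real_, length(beta)))
  names(se) <- names(beta)
  loglik <- sum(y * log(pmax(mu, 1e-300)) +
                  (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(beta = beta, se = se, loglik = loglik, converged = converged,
       n = length(y), n_dropped = n_dropped)
}

#' Logistic association between disease status and a heterozygosity metric
#'
#' Fits case/control status on the z-scored metric with optional covariate
#' adjustment and returns the per-SD odds ratio with a 95% Wald CI. Joint
#' subgroups (`"hip"`, `"knee"`) restrict the cases to that joint while
#' keeping the full control set; the z-scores are those computed over the
#' full analysis set, so effect sizes stay on a common per-SD scale across
#' subgroups.
#'
#' @param profiles het-profile table from [compute_het_profiles()] (one
#'   stratum).
#' @param samples a [sample_table()].
#' @param metric `"het_rate"` or `"het_excess"`.
#' @param subgroup `"all_oa"`, `"hip"` or `"knee"`.
#' @param covariates character subset of `c("age", "sex", "bmi",
#'   "diabetes")`; empty for an unadjusted model. Sex is coded female = 0,
#'   male = 1; diabetes no = 0, yes = 1. Rows with missing covariates are
#'   dropped listwise.
#' @return one-row data.frame with columns `stratum`, `metric`, `subgroup`,
#'   `n_case`, `n_control`, `beta`, `se`, `or_per_sd`, `ci_low`, `ci_high`,
#'   `p`, `covariates`, `converged`.
#' @export
association_test <- function(profiles, samples,
                             metric = c("het_rate", "het_excess"),
                             subgroup = c("all_oa", "hip", "knee"),
                             covariates = character()) {
  metric <- match.arg(metric)
  subgroup <- match.arg(subgroup)
  known_cov <- c("age", "sex", "bmi", "diabetes")
  if (length(covariates) > 0 && !all(covariates %in% known_cov)) {
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, known_cov), collapse = ", "))
  }
  zcol <- paste0("z_", metric)
  stopifnot(zcol %in% names(profiles))
  df <- merge(profiles[, c("sample_id", "stratum", zcol)],
              as.data.frame(samples), by = "sample_id")
  if (subgroup != "all_oa") {
    df <- df[df$status == "control" | df$joint == subgroup, , drop = FALSE]
  }
  if (nrow(df) == 0 || !any(df$status == "case")) {
    stop("empty subgroup '", subgroup, "'")
  }

  y <- as.integer(df$status == "case")
  X <- cbind("(Intercept)" = 1, z = df[[zcol]])
  for (cv in covariates) {
    X <- cbind(X, switch(cv,
      age = df$age,
      sex = as.integer(df$sex == "male"),
      bmi = df$bmi,
      diabetes = as.integer(df$diabetes == "yes")))
    colnames(X)[ncol(X)] <- cv
  }
  fit <- fit_logistic(y, X)
  cc <- stats::complete.cases(y, X)
  b <- fit$beta[["z"]]
  s <- fit$se[["z"]]
  data.frame(
    stratum = df$stratum[1],
    metric = metric,
    subgroup = subgroup,
    n_case = sum(y[cc]),
    n_control = sum(1 - y[cc]),
    beta = b,
    se = s,
    or_per_sd = exp(b),
    ci_low = exp(b - 1.96 * s),
    ci_high = exp(b + 1.96 * s),
    p = 2 * stats::pnorm(-abs(b / s)),
    covariates = paste(covariates, collapse = ","),
    converged = fit$converged,
    stringsAsFactors = FALSE
  )
}

#' Full metric x stratum x subgroup association grid
#'
#' Runs [association_test()] for every combination of the two metrics
#' (HetRate, HetExcess) and three subgroups (all, hip, knee) in each
#' supplied stratum — the 12-cell grid when both conventional MAF strata are
#' given.
#'
#' @param profiles_by_stratum named list of het-profile tables, one per
#'   stratum (names are stratum labels).
#' @param samples a [sample_table()].
#' @param covariates passed to [association_test()].
#' @return data.frame of stacked association rows in deterministic order
#'   (stratum, metric, subgroup).
#' @export
analysis_grid <- function(profiles_by_stratum, samples,
                          covariates = character()) {
  stopifnot(is.list(profiles_by_stratum), length(profiles_by_stratum) >= 1)
  cells <- expand.grid(
    subgroup = c("all_oa", "hip", "knee"),
    metric = c("het_rate", "het_excess"),
    stratum = names(profiles_by_stratum),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(cells)), function(i) {
    association_test(profiles_by_stratum[[cells$stratum[i]]], samples,
                     metric = cells$metric[i], subgroup = cells$subgroup[i],
                     covariates = covariates)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$stratum, res$metric, res$subgroup), ]
  rownames(res) <- NULL
  res
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y paired numeric vectors; pairs with any missing value are
#'   dropped; at least 3 complete pairs and nonzero variance required.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("cannot correlate a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pooled-variance two-sample t-test
#'
#' @param x,y numeric vectors with at least 2 non-missing values each.
#' @return list with `t`, `p`, `df`.
#' @export
students_ttest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  pooled_var <- ((length(x) - 1) * stats::var(x) +
                   (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled_var == 0) stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Two-sample proportion test
#'
#' Chi-square test on the 2x2 table without continuity correction. A
#' warning is attached when any expected cell count falls below 1.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `p`, `chisq`, and `low_expected` flag.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n, n >= 1")
  }
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  low <- any(expected < 1)
  if (any(colSums(tab) == 0)) {
    # all successes or all failures in both groups: proportions equal
    return(list(p = 1, chisq = 0, low_expected = low))
  }
  pt <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE))
  if (low) warning("expected cell count below 1: chi-square approximation unreliable")
  list(p = pt$p.value, chisq = unname(pt$statistic), low_expected = low)
}

#' Cohort descriptive summary
#'
#' Group sizes, mean (SD) age and BMI and percent female for cases overall,
#' hip cases, knee cases and controls, with case-vs-control and hip-vs-knee
#' comparison p-values (pooled t-test for age/BMI, chi-square for sex).
#'
#' @param samples a [sample_table()] with non-empty case and control groups.
#' @return list with `groups` (data.frame) and `tests` (data.frame of
#'   pairwise p-values).
#' @export
cohort_summary <- function(samples) {
  s <- as.data.frame(samples)
  if (!any(s$status == "case") || !any(s$status == "control")) {
    stop("need both cases and controls")
  }
  grp <- list(case = s[s$status == "case", ],
              hip = s[s$joint == "hip", ],
              knee = s[s$joint == "knee", ],
              control = s[s$status == "control", ])
  one <- function(d, name) {
    data.frame(
      group = name,
      n = nrow(d),
      mean_age = mean(d$age, na.rm = TRUE),
      sd_age = stats::sd(d$age, na.rm = TRUE),
      pct_female = 100 * mean(d$sex == "female", na.rm = TRUE),
      mean_bmi = mean(d$bmi, na.rm = TRUE),
      sd_bmi = stats::sd(d$bmi, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  groups <- do.call(rbind, Map(one, grp, names(grp)))
  rownames(groups) <- NULL

  pair_tests <- function(a, b, label) {
    sex_a <- sum(a$sex == "female", na.rm = TRUE)
    sex_b <- sum(b$sex == "female", na.rm = TRUE)
    na <- sum(!is.na(a$sex)); nb <- sum(!is.na(b$sex))
    data.frame(
      comparison = label,
      p_age = tryCatch(students_ttest(a$age, b$age)$p, error = function(e) NA_real_),
      p_bmi = tryCatch(students_ttest(a$bmi, b$bmi)$p, error = function(e) NA_real_),
      p_sex = tryCatch(proportion_test(sex_a, na, sex_b, nb)$p,
                       error = function(e) NA_real_),
      stringsAsFactors = FALSE
    )
  }
  tests <- rbind(pair_tests(grp$case, grp$control, "case_vs_control"),
                 if (nrow(grp$hip) > 1 && nrow(grp$knee) > 1)
                   pair_tests(grp$hip, grp$knee, "hip_vs_knee"))
  list(groups = groups, tests = tests)
}
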