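# Independent oracles used across the suite. Each reimplements the checked
# quantity from its definition, by enumeration or per-cell loops, sharing no
# code with the package internals.

# HWE exact test by direct closed-form enumeration: the conditional
# probability of each attainable heterozygote count given the allele counts,
#   P(h) = n! / (nAA! h! nBB!) * 2^h * r! (2n-r)! / (2n)!
# summed over counts no more probable than the observed one.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  alt <- 2 * n_hom_alt + n_het
  r <- min(alt, 2 * n - alt)
  if (r == 0) return(1)
  hs <- seq(r %% 2, r, by = 2)
  logp <- vapply(hs, function(h) {
    hom_rare <- (r - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(r) + lfactorial(2 * n - r) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(n_het, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# logistic log-likelihood maximized by iterative grid refinement
grid_logistic <- function(y, x, lim = 8) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  b0r <- seq(-lim, lim, length.out = 41)
  b1r <- seq(-lim, lim, length.out = 41)
  best <- c(0, 0)
  for (it in 1:8) {
    grid <- expand.grid(b0 = b0r, b1 = b1r)
    v <- mapply(ll, grid$b0, grid$b1)
    best <- unlist(grid[which.max(v), ], use.names = FALSE)
    w0 <- diff(range(b0r)) / 8
    w1 <- diff(range(b1r)) / 8
    b0r <- seq(best[1] - w0, best[1] + w0, length.out = 21)
    b1r <- seq(best[2] - w1, best[2] + w1, length.out = 21)
  }
  list(beta = best, loglik = ll(best[1], best[2]))
}

# per-cell loop over a call matrix: genotype counts per sample
counts_oracle <- function(calls) {
  out <- data.frame(n_het = integer(nrow(calls)),
                    n_hom_ref = integer(nrow(calls)),
                    n_hom_alt = integer(nrow(calls)),
                    n_missing = integer(nrow(calls)))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(ncol(calls))) {
      v <- calls[i, j]
      if (is.na(v)) out$n_missing[i] <- out$n_missing[i] + 1
      else if (v == 1) out$n_het[i] <- out$n_het[i] + 1
      else if (v == 0) out$n_hom_ref[i] <- out$n_hom_ref[i] + 1
      else out$n_hom_alt[i] <- out$n_hom_alt[i] + 1
    }
  }
  out
}

# per-variant loop: expected heterozygosity per sample
expected_het_oracle <- function(calls, correction = TRUE) {
  n_called_j <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * n_called_j)
  out <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    acc <- 0; k <- 0
    for (j in seq_len(ncol(calls))) {
      if (is.na(calls[i, j])) next
      u <- 2 * p[j] * (1 - p[j])
      if (correction) u <- u * 2 * n_called_j[j] / (2 * n_called_j[j] - 1)
      acc <- acc + u
      k <- k + 1
    }
    out[i] <- if (k > 0) acc / k else NA_real_
  }
  out
}
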