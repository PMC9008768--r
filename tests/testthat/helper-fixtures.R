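# Shared fixtures, generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# small cohort with a clear causal signal, used by several suites
small_cohort <- function() memo("small_cohort", {
  simulate_cohort(sim_config(
    n_per_group = c(CN = 50, MCI = 40, AD = 30),
    n_snps = 60, q_rois = 6, n_causal = 5, effect_size = -0.004,
    seed = 11))
})

# the adjusted X/Y/weights derived from small_cohort
small_adjusted <- function() memo("small_adjusted", {
  co <- small_cohort()
  gf <- fill_missing(qc_filter(co$genotypes)$genotypes)
  mds <- mds_coordinates(ibs_distance(gf), 10)
  fits <- fit_roi_lmms(co$phenotypes, co$covariates)
  rates <- predict_rates(fits, co$covariates)
  w <- compute_weights(prevalence_spec(), table(co$covariates$group))
  list(cohort = co, geno = gf,
       wc = adjust_cohort(gf, rates, mds, co$covariates, w))
})

# brute-force HWE oracle: conditional distribution of the heterozygote
# count given allele counts, computed from the closed-form table
# probabilities (independent of the package's log-space implementation)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- 2 * n_aa + n_Aa
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  prob <- sapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    AA <- n - aa - h
    exp(lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
          h * log(2) +
          lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n))
  })
  prob <- prob / sum(prob)  # guard accumulated rounding
  sum(prob[prob <= prob[hets == n_Aa] + 1e-12])
}

# independent greedy LD-block oracle operating on a precomputed r^2 matrix
ld_blocks_oracle <- function(r2, bp, r2_min = 0.7) {
  p <- length(bp)
  ord <- order(bp)
  block <- rep(NA_integer_, p)
  nb <- 0L
  taken <- rep(FALSE, p)
  for (s in ord) {
    if (taken[s]) next
    mem <- s
    for (t in ord[bp[ord] > bp[s]]) {
      if (taken[t]) next
      if (all(r2[mem, t] > r2_min)) mem <- c(mem, t)
    }
    if (length(mem) > 1) { nb <- nb + 1L; block[mem] <- nb; taken[mem] <- TRUE }
    else taken[s] <- TRUE
  }
  block
}

# brute-force RV coefficient via explicit double sums over covariance
# elements (unweighted, divisor n)
rv_oracle <- function(X, Y) {
  n <- nrow(X)
  covm <- function(A, B) {
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    out <- matrix(0, ncol(A), ncol(B))
    for (k in seq_len(ncol(A))) for (l in seq_len(ncol(B)))
      out[k, l] <- sum(Ac[, k] * Bc[, l]) / n
    out
  }
  sxy <- covm(X, Y); sxx <- covm(X, X); syy <- covm(Y, Y)
  num <- 0; dx <- 0; dy <- 0
  for (k in seq_len(nrow(sxy))) for (l in seq_len(ncol(sxy)))
    num <- num + sxy[k, l]^2
  for (k in seq_len(nrow(sxx))) for (l in seq_len(ncol(sxx)))
    dx <- dx + sxx[k, l]^2
  for (k in seq_len(nrow(syy))) for (l in seq_len(ncol(syy)))
    dy <- dy + syy[k, l]^2
  num / sqrt(dx * dy)
}

# grid-search oracle for the sparse rank-1 objective at lambda_v = 0:
# parameterize the unit b over a spherical angle grid, map through one
# soft-threshold update a(b) = S(K b, lambda) / ||.||, and score ||K'a||
scca_objective_oracle <- function(K, lambda_u, n_theta = 180, n_phi = 360) {
  stopifnot(ncol(K) == 3)
  best <- 0
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi)
  for (th in theta) {
    st <- sin(th); ct <- cos(th)
    for (ph in phi) {
      b <- c(st * cos(ph), st * sin(ph), ct)
      a <- sign(K %*% b) * pmax(abs(K %*% b) - lambda_u, 0)
      na <- sqrt(sum(a^2))
      if (na == 0) next
      obj <- sqrt(sum((crossprod(K, a / na))^2))
      if (obj > best) best <- obj
    }
  }
  best
}
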