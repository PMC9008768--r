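#' Soft-thresholding operator
#'
#' `sign(v) * max(|v| - lambda, 0)`, the shrinkage operator that induces
#' sparsity in the canonical coefficient updates.
#'
#' @param v Numeric vector.
#' @param lambda Threshold, nonnegative.
#' @return Thresholded vector of the same length.
#' @export
soft_threshold <- function(v, lambda) {
  if (lambda < 0) stop("'lambda' must be nonnegative")
  sign(v) * pmax(abs(v) - lambda, 0)
}

#' Weighted cross-correlation matrix for SCCA
#'
#' Standardizes the columns of X and Y to weighted mean 0 / weighted
#' variance 1 and returns the weighted cross-covariance of the standardized
#' columns -- i.e. the weighted cross-correlation matrix the sparse CCA
#' operates on. Zero-variance columns are dropped with a warning.
#'
#' @param X,Y Numeric matrices with aligned rows.
#' @param w Per-subject weights summing to `nrow(X)`; default unit weights.
#' @return p x q cross-correlation matrix with dimnames from X/Y columns.
#' @export
weighted_cross_correlation <- function(X, Y, w = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  Xs <- standardize_weighted(X, w)
  Ys <- standardize_weighted(Y, w)
  crossprod(Xs$m * w, Ys$m) / n
}

# weighted standardization to mean 0 / variance 1 (divisor n convention);
# zero-variance columns are zeroed and reported
standardize_weighted <- function(M, w) {
  M <- as.matrix(M)
  n <- nrow(M)
  mu <- colSums(M * w) / sum(w)
  Mc <- sweep(M, 2, mu)
  v <- colSums(Mc^2 * w) / n
  zero <- v <= 0
  sd <- sqrt(ifelse(zero, 1, v))
  list(m = sweep(Mc, 2, sd, "/") * rep(!zero, each = n), zero = zero)
}

#' Sparse canonical correlation by soft-thresholded rank-1 approximation
#'
#' Alternating power-iteration scheme on the (weighted) cross-correlation
#' matrix K: update `a <- K b`, soft-threshold by `lambda_u`, renormalize to
#' unit norm; update `b <- t(K) a`, soft-threshold by `lambda_v`,
#' renormalize; iterate to convergence. With both penalties zero this is
#' power iteration for the leading singular-vector pair of K. The sign is
#' fixed so the largest-magnitude entry of `a` is positive.
#'
#' @param K p x q cross-correlation matrix (see
#'   [weighted_cross_correlation()]).
#' @param lambda_u Soft-threshold penalty on the SNP coefficients `a`.
#' @param lambda_v Penalty on the endophenotype coefficients `b`; default 0
#'   (sparse SNP combination against a non-sparse imaging combination).
#' @param init Optional initial `b`; default the leading right singular
#'   vector of K.
#' @param tol Convergence tolerance on the max absolute coefficient change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return Object of class `"scca_fit"`: list with sparse coefficient
#'   vectors `a` (length p) and `b` (length q), penalties, `n_iter`,
#'   `converged`, `empty` (all-zero model flag), the objective `a' K b`
#'   and the `penalized_objective` the alternating updates ascend.
#' @export
scca_fit <- function(K, lambda_u, lambda_v = 0, init = NULL,
                     tol = 1e-6, max_iter = 1000) {
  K <- as.matrix(K)
  if (!all(is.finite(K))) stop("'K' must be finite")
  p <- nrow(K); q <- ncol(K)
  empty_fit <- function(n_iter) structure(
    list(a = numeric(p), b = numeric(q), lambda_u = lambda_u,
         lambda_v = lambda_v, n_iter = n_iter, converged = TRUE,
         empty = TRUE, objective = 0),
    class = "scca_fit")

  if (all(K == 0)) return(empty_fit(0L))
  b <- if (is.null(init)) svd(K, nu = 0, nv = 1)$v[, 1] else init / l2(init)

  a_old <- numeric(p); b_old <- b
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a <- soft_threshold(drop(K %*% b), lambda_u)
    na <- l2(a)
    if (na == 0) return(empty_fit(it))
    a <- a / na
    b <- soft_threshold(drop(crossprod(K, a)), lambda_v)
    nb <- l2(b)
    if (nb == 0) return(empty_fit(it))
    b <- b / nb
    if (max(abs(a - a_old)) < tol && max(abs(b - b_old)) < tol) {
      converged <- TRUE
      break
    }
    a_old <- a; b_old <- b
  }
  i <- which.max(abs(a))
  if (a[i] < 0) { a <- -a; b <- -b }
  names(a) <- rownames(K); names(b) <- colnames(K)
  obj <- drop(crossprod(a, K %*% b))
  structure(list(a = a, b = b, lambda_u = lambda_u, lambda_v = lambda_v,
                 n_iter = it, converged = converged, empty = FALSE,
                 objective = obj,
                 # the quantity the alternating updates ascend
                 penalized_objective = obj - lambda_u * sum(abs(a)) -
                   lambda_v * sum(abs(b))),
            class = "scca_fit")
}

l2 <- function(x) sqrt(sum(x^2))

#' @export
print.scca_fit <- function(x, ...) {
  cat(sprintf("Sparse CCA fit: %d / %d nonzero SNP coefficients (lambda_u = %g)\n",
              sum(x$a != 0), length(x$a), x$lambda_u))
  cat(sprintf("  objective a'Kb = %.5g; %s in %d iterations%s\n",
              x$objective,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$empty) "; model fully thresholded (empty)" else ""))
  invisible(x)
}

#' @export
coef.scca_fit <- function(object, ...) list(a = object$a, b = object$b)

#' Cross-validated soft-threshold penalty search
#'
#' Ten-fold cross-validation over a penalty grid: for each grid value, fit
#' the sparse CCA on nine folds and evaluate the correlation of the
#' canonical variates `cor(X_test a, Y_test b)` on the held-out fold; the
#' chosen penalty maximizes the sum of test-set correlations (ties broken
#' toward the smaller penalty). With diffuse low signal this criterion is
#' known to retain nearly all variables -- the motivation for the
#' fixed-fraction calibration in [calibrate_penalty_to_fraction()].
#'
#' @param X,Y Adjusted data matrices with aligned rows.
#' @param w Per-subject weights; default unit.
#' @param grid Penalty grid; default `{0} U {1e-4 + 0.0005 k} <= 0.1`.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List with `lambda_u` (chosen) and `cv_table` (grid, summed test
#'   correlation, mean selected fraction).
#' @export
cv_select_penalty <- function(X, Y, w = NULL, grid = penalty_grid(),
                              folds = 10, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  if (!length(grid)) stop("empty penalty grid")
  rng <- local_rng(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  rng()

  score <- numeric(length(grid))
  frac <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    cors <- numeric(folds)
    fr <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      K <- weighted_cross_correlation(X[tr, , drop = FALSE],
                                      Y[tr, , drop = FALSE], w[tr])
      fit <- scca_fit(K, lambda_u = grid[gi])
      fr[f] <- mean(fit$a != 0)
      u <- as.matrix(X[!tr, , drop = FALSE]) %*% fit$a
      v <- as.matrix(Y[!tr, , drop = FALSE]) %*% fit$b
      cors[f] <- if (fit$empty || stats::sd(u) == 0 || stats::sd(v) == 0) 0
        else stats::cor(u, v)
    }
    score[gi] <- sum(cors)
    frac[gi] <- mean(fr)
  }
  best <- which(score == max(score))
  lambda <- min(grid[best])
  list(lambda_u = lambda,
       cv_table = data.frame(lambda_u = grid, sum_test_cor = score,
                             mean_selected_fraction = frac))
}

#' Default penalty search grid
#'
#' `{0, 1e-4, 1e-4 + 0.0005, 1e-4 + 0.001, ...}` up to 0.1.
#' @return Numeric vector of penalties.
#' @export
penalty_grid <- function() {
  c(0, seq(1e-4, 0.1, by = 5e-4))
}

#' Calibrate the SNP penalty to a target selected fraction
#'
#' Bisection on `lambda_u` until the fraction of nonzero SNP coefficients in
#' the sparse CCA fit is within tolerance of the target (the study design
#' targets ~10%, the fraction of SNPs plausibly associated with the
#' phenotypes). Support size is nonincreasing in the penalty, which the
#' search verifies as it proceeds; if the target falls between achievable
#' support sizes, the nearest achievable penalty is returned with a warning.
#'
#' @param K Cross-correlation matrix.
#' @param target_fraction Desired fraction of SNPs selected (default 0.10).
#' @param tol_fraction Acceptable deviation (default 0.01).
#' @param max_steps Bisection step cap (default 60).
#' @return List with `lambda_u`, `fraction` achieved, and `fit`.
#' @export
calibrate_penalty_to_fraction <- function(K, target_fraction = 0.10,
                                          tol_fraction = 0.01,
                                          max_steps = 60) {
  if (target_fraction <= 0 || target_fraction > 1)
    stop("'target_fraction' must be in (0, 1]")
  K <- as.matrix(K)
  p <- nrow(K)
  frac_at <- function(lam) {
    fit <- scca_fit(K, lambda_u = lam)
    list(fit = fit, frac = mean(fit$a != 0))
  }
  lo <- 0
  at_lo <- frac_at(0)
  if (target_fraction >= at_lo$frac - tol_fraction)  # lambda = 0 already at/below target density
    return(list(lambda_u = 0, fraction = at_lo$frac, fit = at_lo$fit))
  hi <- max(abs(K)) * sqrt(ncol(K))   # ample: thresholds everything
  best <- at_lo; best_lam <- 0
  for (s in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    at <- frac_at(mid)
    if (abs(at$frac - target_fraction) < abs(best$frac - target_fraction)) {
      best <- at; best_lam <- mid
    }
    if (abs(at$frac - target_fraction) <= tol_fraction)
      return(list(lambda_u = mid, fraction = at$frac, fit = at$fit))
    if (at$frac > target_fraction) lo <- mid else hi <- mid
  }
  warning(sprintf(
    "target fraction %.3f not reachable within tolerance; returning nearest achieved %.3f",
    target_fraction, best$frac))
  list(lambda_u = best_lam, fraction = best$frac, fit = best$fit)
}

#' Bootstrap variable-importance probabilities for SNP selection
#'
#' Bootstrap-enhanced sparse CCA: subjects are resampled with replacement
#' within each diagnostic group (preserving the biased design), the weighted
#' cross-correlation matrix is recomputed, and the sparse CCA is refit at
#' the fixed, calibrated penalty. The variable importance probability of
#' SNP k is the fraction of bootstrap replicates in which its coefficient is
#' nonzero; the exclusion probability is `VEP = 1 - VIP`. Replicates in
#' which a resampled SNP column becomes constant contribute a zero
#' coefficient for that SNP; fully degenerate replicate fits count as
#' selecting nothing.
#'
#' @param X,Y Adjusted data matrices with aligned rows.
#' @param w Per-subject weights (travel with the subjects when resampled).
#' @param groups Per-subject diagnostic labels used to stratify the
#'   resampling.
#' @param lambda_u Fixed soft-threshold penalty (see
#'   [calibrate_penalty_to_fraction()]).
#' @param B Number of bootstrap replicates (the study design used 100,000;
#'   scale to the problem at hand).
#' @param seed Integer master seed; replicate streams derive from it.
#' @param snp_ids Optional SNP identifiers (default colnames of X).
#' @return Object of class `"vip_table"`: data frame with `id`, `vip`,
#'   `vep`, `n_selected`, plus attributes `B`, `lambda_u`, `seed`.
#' @export
bootstrap_vip <- function(X, Y, w = NULL, groups, lambda_u, B = 1000,
                          seed = 1, snp_ids = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (B < 1) stop("'B' must be at least 1")
  if (length(groups) != n) stop("one group label per subject required")
  if (is.null(w)) w <- rep(1, n)
  if (is.null(snp_ids)) snp_ids <- colnames(X)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(X)))

  strata <- split(seq_len(n), groups)
  n_sel <- integer(ncol(X))
  degenerate <- 0L
  rng <- local_rng(seed)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(strata, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]), use.names = FALSE)
    K <- weighted_cross_correlation(X[idx, , drop = FALSE],
                                    Y[idx, , drop = FALSE], w[idx])
    fit <- scca_fit(K, lambda_u = lambda_u)
    if (fit$empty) degenerate <- degenerate + 1L
    else n_sel <- n_sel + (fit$a != 0)
  }
  rng()

  out <- data.frame(id = snp_ids, vip = n_sel / B, vep = 1 - n_sel / B,
                    n_selected = n_sel, stringsAsFactors = FALSE)
  structure(out, class = c("vip_table", "data.frame"),
            B = B, lambda_u = lambda_u, seed = seed,
            degenerate_replicates = degenerate)
}

#' @export
print.vip_table <- function(x, ...) {
  cat(sprintf("Bootstrap VIP table: %d SNPs, B = %d replicates, lambda_u = %g\n",
              nrow(x), attr(x, "B"), attr(x, "lambda_u")))
  cat(sprintf("  VIP >= 0.5: %d SNPs; VIP >= 0.9: %d SNPs\n",
              sum(x$vip >= 0.5), sum(x$vip >= 0.9)))
  NextMethod()
}

#' Manhattan-style plot of variable exclusion probabilities
#'
#' Plots `-log10(VEP)` per SNP (so VIP >= 0.9 appears at or above 1), with
#' reference lines at the priority (VIP = 0.5) and top-hit (VIP = 0.9)
#' cut-offs.
#'
#' @param x A `"vip_table"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.vip_table <- function(x, ...) {
  B <- attr(x, "B")
  vep <- pmax(x$vep, 1 / (2 * B))    # clip so selected-always SNPs plot finitely
  graphics::plot(seq_len(nrow(x)), -log10(vep), pch = 20,
                 xlab = "SNP index", ylab = expression(-log[10](VEP)), ...)
  graphics::abline(h = -log10(0.5), lty = 2)
  graphics::abline(h = -log10(0.1), lty = 3)
  invisible(x)
}

#' Select priority and top-hit SNP sets from a VIP table
#'
#' Inclusive thresholds: the priority set holds SNPs with VIP at or above
#' the liberal cut (default 0.5), the top-hit set those at or above the
#' stringent cut (default 0.9); top-hit is always a subset of priority.
#'
#' @param vip A `"vip_table"` from [bootstrap_vip()].
#' @param priority_cut,top_cut Inclusive VIP thresholds, `priority_cut <=
#'   top_cut`, both in (0, 1].
#' @return List with character vectors `priority` and `top_hit` and their
#'   sizes.
#' @export
select_refined_sets <- function(vip, priority_cut = 0.5, top_cut = 0.9) {
  if (priority_cut <= 0 || top_cut > 1 || priority_cut > top_cut)
    stop("cuts must satisfy 0 < priority_cut <= top_cut <= 1")
  priority <- vip$id[vip$vip >= priority_cut]
  top_hit <- vip$id[vip$vip >= top_cut]
  if (!length(priority)) warning("empty priority set")
  list(priority = priority, top_hit = top_hit,
       n_priority = length(priority), n_top_hit = length(top_hit))
}
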