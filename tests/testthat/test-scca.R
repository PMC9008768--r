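test_that("soft-thresholding shrinks toward zero elementwise", {
  v <- c(0.5, -0.2, 0.1)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(v, 0.15), c(0.35, -0.05, 0))
  expect_equal(soft_threshold(v, 0.6), c(0, 0, 0))
  expect_error(soft_threshold(v, -1), "nonnegative")
})

test_that("unpenalized fits recover the leading singular-vector pair", {
  set.seed(3)
  # exact rank-1 matrix
  u <- rnorm(6); u <- u / sqrt(sum(u^2))
  v <- rnorm(4); v <- v / sqrt(sum(v^2))
  K <- 2.5 * tcrossprod(u, v)
  fit <- scca_fit(K, 0)
  expect_lt(min(abs(sum(fit$a * u)), abs(sum(fit$a * -u))) - 1, 1e-8)
  expect_gt(abs(sum(fit$a * u)), 1 - 1e-8)
  expect_gt(abs(sum(fit$b * v)), 1 - 1e-8)

  # general random matrices: cosine similarity with svd > 1 - 1e-8
  for (s in 1:3) {
    set.seed(100 + s)
    K <- matrix(rnorm(8 * 5), 8)
    fit <- scca_fit(K, 0)
    sv <- svd(K, nu = 1, nv = 1)
    expect_gt(abs(sum(fit$a * sv$u[, 1])), 1 - 1e-8)
    expect_gt(abs(sum(fit$b * sv$v[, 1])), 1 - 1e-8)
    expect_equal(fit$objective, sv$d[1], tolerance = 1e-8)
  }
})

test_that("penalized objective matches a grid-search oracle on 4x3 problems", {
  for (s in 1:2) {
    set.seed(200 + s)
    K <- matrix(rnorm(12), 4, 3)
    for (lam in c(0.1, 0.3)) {
      fit <- scca_fit(K, lam)
      if (fit$empty) next
      oracle <- scca_objective_oracle(K, lam)
      expect_equal(fit$objective, oracle, tolerance = 0.01,
                   label = sprintf("objective vs oracle (seed %d, lambda %.1f)", s, lam))
    }
  }
})

test_that("large penalties empty the model and the objective is monotone over iterations", {
  set.seed(7)
  K <- matrix(rnorm(20), 5, 4)
  big <- scca_fit(K, lambda_u = 10)
  expect_true(big$empty)
  expect_equal(big$a, rep(0, 5))

  # the alternating updates ascend the penalized objective
  # a'Kb - lambda_u ||a||_1; iterating further can only improve it
  one_step <- scca_fit(K, 0.2, max_iter = 1)
  full <- scca_fit(K, 0.2)
  expect_gte(full$penalized_objective, one_step$penalized_objective - 1e-10)
})

test_that("support size is nonincreasing in the penalty", {
  set.seed(16)
  K <- matrix(rnorm(40 * 6), 40)
  supp <- vapply(seq(0, 0.6, by = 0.05), function(l)
    sum(scca_fit(K, l)$a != 0), numeric(1))
  expect_true(all(diff(supp) <= 0))
})

test_that("penalty calibration reaches the target selected fraction", {
  set.seed(23)
  K <- matrix(rnorm(1000 * 8, sd = 0.1), 1000)
  cal <- calibrate_penalty_to_fraction(K, target_fraction = 0.10)
  expect_gte(cal$fraction, 0.09)
  expect_lte(cal$fraction, 0.11)
  # a full-density target needs no thresholding at all
  cal1 <- calibrate_penalty_to_fraction(K, target_fraction = 1)
  expect_equal(cal1$lambda_u, 0)
  # unreachable resolution warns and returns nearest achievable
  expect_warning(calibrate_penalty_to_fraction(matrix(c(1, 1, 1, 1), 2),
                                               target_fraction = 0.25,
                                               tol_fraction = 0.001),
                 "not reachable")
})

test_that("prediction-optimal penalties barely select under diffuse signal", {
  # diffuse truth: every SNP contributes, with varying small weights; the
  # prediction criterion then favors the densest model on the grid
  set.seed(77)
  n <- 300; p <- 40
  X <- matrix(rnorm(n * p), n)
  beta <- runif(p, 0.5, 1.5) / sqrt(p)
  Y <- matrix(X %*% beta + rnorm(n, sd = 0.8), n)
  sel <- cv_select_penalty(X, Y, grid = c(0, 0.02, 0.05, 0.1, 0.2),
                           folds = 5, seed = 2)
  frac <- sel$cv_table$mean_selected_fraction[sel$cv_table$lambda_u == sel$lambda_u]
  expect_gt(frac, 0.98)  # essentially no variable selection

  single <- cv_select_penalty(X, Y, grid = 0.02, folds = 5, seed = 2)
  expect_equal(single$lambda_u, 0.02)
})

test_that("bootstrap VIPs separate causal from null SNPs and stay in [0,1]", {
  adj <- small_adjusted()
  wc <- adj$wc
  K <- weighted_cross_correlation(wc$X, wc$Y, wc$w)
  cal <- calibrate_penalty_to_fraction(K, 0.10)
  vt <- bootstrap_vip(wc$X, wc$Y, wc$w, wc$groups, cal$lambda_u,
                      B = 300, seed = 2)
  expect_true(all(vt$vip >= 0 & vt$vip <= 1))
  causal <- adj$cohort$truth$causal_snp_ids
  # causal SNPs should clearly outrank the background; SNPs sharing an LD
  # block with a causal SNP legitimately absorb part of the signal, so the
  # full-cohort margin criterion is checked at study scale elsewhere
  expect_gt(mean(vt$vip[vt$id %in% causal]),
            mean(vt$vip[!vt$id %in% causal]) + 0.1)

  b1 <- bootstrap_vip(wc$X[, 1:10], wc$Y, wc$w, wc$groups, cal$lambda_u,
                      B = 1, seed = 3)
  expect_true(all(b1$vip %in% c(0, 1)))
})

test_that("under a pure null the VIPs concentrate near the calibrated sparsity", {
  set.seed(55)
  n <- 80; p <- 40
  X <- matrix(rnorm(n * p), n)
  Y <- matrix(rnorm(n * 4), n)
  groups <- rep(c("CN", "MCI", "AD"), length.out = n)
  K <- weighted_cross_correlation(X, Y)
  cal <- calibrate_penalty_to_fraction(K, 0.10)
  vt <- bootstrap_vip(X, Y, NULL, groups, cal$lambda_u, B = 200, seed = 8)
  expect_gt(mean(vt$vip), 0.02)
  expect_lt(mean(vt$vip), 0.30)
  expect_lt(max(vt$vip), 0.9)  # no SNP should look like a stable hit
})

test_that("refined sets use inclusive thresholds and nest", {
  vip <- structure(data.frame(id = c("a", "b", "c"),
                              vip = c(0.95, 0.5, 0.1),
                              vep = c(0.05, 0.5, 0.9),
                              n_selected = c(95, 50, 10)),
                   class = c("vip_table", "data.frame"), B = 100,
                   lambda_u = 0.1, seed = 1)
  sets <- select_refined_sets(vip)
  expect_equal(sets$priority, c("a", "b"))   # 0.5 is inclusive
  expect_equal(sets$top_hit, "a")
  expect_true(all(sets$top_hit %in% sets$priority))
  expect_warning(select_refined_sets(vip, priority_cut = 0.99, top_cut = 0.99),
                 "empty priority")
  expect_error(select_refined_sets(vip, priority_cut = 0.9, top_cut = 0.5))
})
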