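toy_geno <- function(values, chr = NULL, bp = NULL) {
  p <- ncol(values)
  genotype_matrix(values,
                  data.frame(id = paste0("s", seq_len(p)),
                             chr = if (is.null(chr)) rep(1, p) else chr,
                             bp = if (is.null(bp)) seq_len(p) * 1000 else bp))
}

test_that("exact HWE test matches the enumeration oracle on small tables", {
  expect_equal(hwe_exact_pvalue(1, 2, 1), 1)        # modal table
  expect_equal(hwe_exact_pvalue(7, 0, 0), 1)        # only one table possible
  # all-heterozygote tables are not modal: p strictly below 1
  for (n in c(4, 6, 8)) expect_lt(hwe_exact_pvalue(0, n, 0), 1)
  # sweep of tables with counts <= 30 against the closed-form oracle
  for (tab in list(c(10, 8, 2), c(30, 0, 5), c(12, 12, 6), c(0, 4, 0),
                   c(25, 10, 1), c(3, 3, 3), c(20, 5, 5), c(1, 1, 28))) {
    expect_equal(hwe_exact_pvalue(tab[1], tab[2], tab[3]),
                 hwe_oracle(tab[1], tab[2], tab[3]),
                 tolerance = 1e-12,
                 label = paste("table", paste(tab, collapse = "/")))
  }
  expect_error(hwe_exact_pvalue(0, 0, 0), "zero")
})

test_that("qc_filter applies call-rate, MAF and HWE filters in order and is idempotent", {
  set.seed(4)
  n <- 100
  v <- cbind(
    snp_mono = rep(0, n),                                  # MAF 0
    snp_miss = c(rep(NA, 6), rlnorm(0), rbinom(n - 6, 2, 0.3)),  # 6% missing
    snp_hwe = rep(c(0, 2), each = n / 2),                  # no hets at MAF 0.5
    snp_ok1 = rbinom(n, 2, 0.3),
    snp_ok2 = rbinom(n, 2, 0.4))
  g <- toy_geno(v)
  res <- qc_filter(g)
  expect_setequal(res$genotypes$snps$id, c("s4", "s5"))
  expect_equal(res$report$dropped[res$report$filter == "call_rate"], 1)
  expect_equal(res$report$dropped[res$report$filter == "maf"], 1)
  expect_equal(res$report$dropped[res$report$filter == "hwe"], 1)

  twice <- qc_filter(res$genotypes)
  expect_identical(twice$genotypes$values, res$genotypes$values)
  expect_true(all(twice$report$dropped == 0))
})

test_that("sex-chromosome SNPs are excluded and region restriction is closed-interval", {
  v <- matrix(rbinom(4 * 5, 2, 0.4), 4)
  g <- genotype_matrix(v, data.frame(
    id = paste0("s", 1:5),
    chr = c("1", "1", "X", "2", "1"),
    bp = c(100e6, 83e6, 50e6, 83e6, 200e6)))
  regions <- data.frame(chr = 1, band = "p31.1-q31.1", start_mb = 83, end_mb = 185)
  kept <- restrict_to_regions(g, regions)
  # inside, exact lower boundary kept; X and off-chromosome and beyond-end dropped
  expect_setequal(kept$snps$id, c("s1", "s2"))
  expect_true(all(kept$snps$region == "1p31.1-q31.1"))

  qc <- qc_filter(g, hwe_alpha = 1e-30, maf_min = 0)
  expect_false("s3" %in% qc$genotypes$snps$id)
})

test_that("missing-fill uses the rounded SNP mean and leaves no gaps", {
  v <- matrix(c(0, 1, 1, NA,
                2, 2, 0, 0), 4)
  g <- toy_geno(v)
  filled <- fill_missing(g)
  expect_equal(filled$values[4, 1], 1)    # round(2/3) = 1
  expect_identical(filled$values[, 2], g$values[, 2])  # untouched column
  expect_false(anyNA(filled$values))
  expect_identical(fill_missing(filled)$values, filled$values)
})

test_that("IBS distance matches the allele-sharing formula", {
  v <- rbind(a = c(0, 1), b = c(2, 1), c = c(0, 2))
  g <- toy_geno(v)
  D <- ibs_distance(g)
  # hand: d(a,b) = 1 - (1/4)((2-2)+(2-0)) = 0.5
  #       d(a,c) = 1 - (1/4)((2-0)+(2-1)) = 0.25
  #       d(b,c) = 1 - (1/4)((2-2)+(2-1)) = 0.75
  expect_equal(D["a", "b"], 0.5)
  expect_equal(D["a", "c"], 0.25)
  expect_equal(D["b", "c"], 0.75)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))

  same <- toy_geno(rbind(x = c(1, 2, 0), y = c(1, 2, 0)))
  expect_equal(ibs_distance(same)["x", "y"], 0)
  opp <- toy_geno(rbind(x = c(0, 0), y = c(2, 2)))
  expect_equal(ibs_distance(opp)["x", "y"], 1)
})

test_that("classical MDS reproduces Euclidean configurations and known eigenvalues", {
  set.seed(9)
  P <- matrix(rnorm(20 * 3), 20)
  D <- as.matrix(dist(P))
  mds <- mds_coordinates(D, 3)
  expect_equal(as.matrix(dist(mds$coords)), D, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(abs(colMeans(mds$coords)) < 1e-8))
  # rotation equivariance: distances unchanged under orthogonal transform
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  D2 <- as.matrix(dist(P %*% Q))
  mds2 <- mds_coordinates(D2, 3)
  expect_equal(as.matrix(dist(mds2$coords)), D, ignore_attr = TRUE,
               tolerance = 1e-8)

  # unit square: centered Gram matrix has eigenvalues (1, 1, 0, 0)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  msq <- mds_coordinates(as.matrix(dist(sq)), 2)
  expect_equal(sort(msq$eig, decreasing = TRUE)[1:2], c(1, 1), tolerance = 1e-10)
  expect_equal(msq$positive_mass_captured, 1)

  expect_warning(mds_coordinates(matrix(0, 4, 4), 3), "padding")
})

test_that("LD r-squared matches Pearson and is coding-invariant", {
  g <- toy_geno(cbind(c(0, 1, 1, 2), c(0, 1, 2, 2)))
  expect_equal(ld_r2(g, "s1", "s1"), 1)
  expect_equal(ld_r2(g, "s1", "s2"), 8 / 11)  # hand: Sxy^2/(Sxx Syy) = 4/5.5
  expect_equal(ld_r2(g, "s1", "s2"), ld_r2(g, "s2", "s1"))
  flipped <- toy_geno(cbind(c(0, 1, 1, 2), 2 - c(0, 1, 2, 2)))
  expect_equal(ld_r2(flipped, "s1", "s2"), 8 / 11)
  mono <- toy_geno(cbind(c(1, 1, 1, 1), c(0, 1, 2, 2)))
  expect_error(ld_r2(mono, "s1", "s2"), "monomorphic")
})

test_that("LD blocks require all pairwise r2 above threshold (clique rule)", {
  set.seed(21)
  n <- 60
  base <- rbinom(n, 2, 0.5)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- 2 - x[i]; x }
  A <- base; B <- flip(base, 3); C <- flip(base, 25)  # A-B tight, C loose
  g <- toy_geno(cbind(A, B, C), bp = c(1000, 2000, 3000))
  r_ab <- ld_r2(g, "s1", "s2"); r_ac <- ld_r2(g, "s1", "s3")
  stopifnot(r_ab > 0.7, r_ac < 0.7)   # premises of the scenario
  bl <- ld_blocks(g)
  expect_equal(bl$block[bl$id %in% c("s1", "s2")], c(1L, 1L))
  expect_true(is.na(bl$block[bl$id == "s3"]))

  # all three mutually tight: one block of 3
  g3 <- toy_geno(cbind(base, flip(base, 2), flip(base, 3)),
                 bp = c(1000, 2000, 3000))
  bl3 <- ld_blocks(g3)
  expect_equal(bl3$block, c(1L, 1L, 1L))

  # nothing correlated: no blocks at all
  g0 <- toy_geno(cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5)),
                 bp = c(1000, 2000))
  expect_true(all(is.na(ld_blocks(g0)$block)))
})

test_that("greedy LD grouping matches an independent brute-force pass on 8 SNPs", {
  set.seed(33)
  n <- 80
  base1 <- rbinom(n, 2, 0.4); base2 <- rbinom(n, 2, 0.5)
  jitter <- function(x, k) { i <- sample(n, k); x[i] <- sample(0:2, k, TRUE); x }
  v <- cbind(base1, jitter(base1, 4), jitter(base1, 30), base2,
             jitter(base2, 3), jitter(base2, 5), rbinom(n, 2, 0.3),
             jitter(base1, 6))
  bp <- seq(1000, by = 1000, length.out = 8)
  g <- toy_geno(v, bp = bp)
  r2 <- cor(v)^2
  expect_equal(ld_blocks(g)$block, ld_blocks_oracle(r2, bp))
})
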