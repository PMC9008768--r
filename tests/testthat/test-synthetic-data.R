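test_that("configuration invariants are enforced", {
  expect_error(sim_config(prevalence = c(CN = 0.5, MCI = 0.3, AD = 0.3)),
               "sum to 1")
  expect_error(sim_config(n_snps = 50,
                          block_spec = default_block_spec(40)),
               "block sizes")
  expect_error(sim_config(n_causal = 1000, n_snps = 10), "n_causal")
  expect_error(sim_config(maf_range = c(0.01, 0.4)), "maf_range")
  bs <- default_block_spec(20); bs$rho <- 1
  expect_error(sim_config(n_snps = 20, block_spec = bs), "rho")
})

test_that("block correlation controls genotype r2 and marginals follow the MAF", {
  n <- 2000
  bs0 <- data.frame(region = "1p31.1-q31.1", chr = 1, start_bp = 83e6,
                    end_bp = 83e6 + 9000, size = 10, rho = 0)
  cfg0 <- sim_config(n_per_group = c(CN = n, MCI = 0, AD = 0), n_snps = 10,
                     block_spec = bs0, missing_rate = 0,
                     ancestry_strength = 0, seed = 101)
  g0 <- simulate_genotypes(cfg0)
  r2 <- cor(g0$values)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.02)

  bs95 <- transform(bs0, rho = 0.95)
  cfg95 <- sim_config(n_per_group = c(CN = n, MCI = 0, AD = 0), n_snps = 10,
                      block_spec = bs95, missing_rate = 0,
                      ancestry_strength = 0, seed = 102)
  g95 <- simulate_genotypes(cfg95)
  r2b <- cor(g95$values)^2
  expect_gt(median(r2b[upper.tri(r2b)]), 0.7)

  # sample MAF within the 3-sigma binomial band of the generating MAF
  maf_gen <- attr(g95, "maf")
  maf_obs <- colMeans(g95$values) / 2
  band <- 3 * sqrt(maf_gen * (1 - maf_gen) / (2 * n))
  expect_true(all(abs(maf_obs - maf_gen) <= band + 1e-12))
})

test_that("seeded simulation is bit-reproducible and annotations are consistent", {
  cfg <- sim_config(n_per_group = c(CN = 30, MCI = 20, AD = 10),
                    n_snps = 30, q_rois = 3, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$covariates, b$covariates)
  expect_true(all(a$truth$causal_snp_ids %in% a$genotypes$snps$id))
  expect_equal(length(a$truth$causal_effects),
               length(a$truth$causal_snp_ids))
  expect_true(all(a$genotypes$snps$region %in%
                    c("1p31.1-q31.1", "6p21.1-q15", "10p14-q24", "19p13.3-qter")))
})

test_that("without noise or random slopes every trajectory is exactly linear", {
  cfg <- sim_config(n_per_group = c(CN = 10, MCI = 5, AD = 5), n_snps = 10,
                    q_rois = 2, n_causal = 0,
                    variance_components = c(intercept = 0.02, slope = 0,
                                            noise = 0),
                    dropout_prob = 0, missing_rate = 0, seed = 13)
  co <- simulate_cohort(cfg)
  for (key in split(co$phenotypes, paste(co$phenotypes$subject_id,
                                         co$phenotypes$roi))) {
    fit <- lm(value ~ month, key)
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
})

test_that("every subject keeps a baseline and at least one follow-up per ROI", {
  cfg <- sim_config(n_per_group = c(CN = 30, MCI = 20, AD = 10), n_snps = 10,
                    q_rois = 4, dropout_prob = 0.45, seed = 5)
  co <- simulate_cohort(cfg)
  by_cell <- split(co$phenotypes$month,
                   paste(co$phenotypes$subject_id, co$phenotypes$roi))
  expect_true(all(vapply(by_cell, function(m) any(m == 0) && any(m > 0),
                         logical(1))))
})

test_that("a cohort round-trips losslessly through the PLINK-text writers", {
  cfg <- sim_config(n_per_group = c(CN = 15, MCI = 10, AD = 8), n_snps = 20,
                    q_rois = 2, missing_rate = 0.05, seed = 29)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(unname(back$genotypes$values), unname(co$genotypes$values))
  expect_equal(back$phenotypes$value, co$phenotypes$value)
  expect_identical(back$covariates, co$covariates)
  expect_identical(back$truth$causal_snp_ids, co$truth$causal_snp_ids)
  expect_equal(length(back$truth$causal_snp_ids), cfg$n_causal)

  # PLINK convention: missing genotypes are written as "0 0"
  ped <- readLines(file.path(dir, "cohort.ped"))
  fields <- strsplit(ped[which(rowSums(is.na(co$genotypes$values)) > 0)[1]],
                     " ")[[1]]
  k <- which(is.na(co$genotypes$values[which(rowSums(is.na(co$genotypes$values)) > 0)[1], ]))[1]
  expect_equal(fields[6 + 2 * k - 1], "0")
  expect_equal(fields[6 + 2 * k], "0")
})

test_that("inferred minor alleles agree with annotations when unambiguous", {
  cfg <- sim_config(n_per_group = c(CN = 200, MCI = 0, AD = 0), n_snps = 10,
                    maf_range = c(0.05, 0.35), missing_rate = 0, seed = 17)
  g <- simulate_genotypes(cfg)
  dir <- withr::local_tempdir()
  write_ped(g, file.path(dir, "x"))
  back <- read_ped(file.path(dir, "x.ped"), file.path(dir, "x.map"))
  expect_identical(unname(back$values), unname(g$values))
  expect_identical(back$snps$minor, g$snps$minor)
})
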