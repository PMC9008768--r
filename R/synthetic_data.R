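#' Configuration for the synthetic imaging-genetics cohort generator
#'
#' Captures the statistical design the analysis assumes: a three-group
#' case-control cohort sampled with bias relative to population prevalences,
#' SNPs in correlated LD blocks inside labelled linkage regions, and
#' longitudinal region-of-interest (ROI) trajectories following the
#' random-intercept + random-slope mixed model, with a sparse causal SNP
#' subset acting on the atrophy slopes and ancestry/APOE confounding
#' injected into both data blocks.
#'
#' Defaults mirror the discovery-cohort design: group counts 179/296/157
#' (CN/MCI/AD), prevalences 0.875/0.05/0.075, 56 ROIs measured at months
#' 0/6/12/18/24. The SNP panel defaults to a desk-scale 300 markers in
#' blocks of 10 with within-block latent correlation 0.85, placed in the
#' published autosomal linkage-region bands.
#'
#' @param n_per_group Named counts for CN, MCI, AD.
#' @param prevalence Named population prevalences (must sum to 1).
#' @param n_snps Total number of SNPs; must equal the sum of block sizes.
#' @param block_spec Data frame with one row per LD block: `region`, `chr`,
#'   `start_bp`, `end_bp`, `size`, `rho` (within-block latent correlation,
#'   in \[0, 1)). Default built by [default_block_spec()].
#' @param maf_range Interval of minor-allele frequencies, within
#'   \[0.05, 0.5\].
#' @param n_causal Number of causal SNPs (effects on atrophy slopes).
#' @param effect_size Slope shift per minor allele, units per month.
#' @param q_rois Number of ROIs (default 56).
#' @param visit_months Visit schedule (default 0, 6, 12, 18, 24).
#' @param variance_components Named vector `(intercept, slope, noise)` of
#'   variances for the random intercept, random slope and residual error.
#' @param dropout_prob Per-follow-up-visit missingness probability for the
#'   phenotype records (baseline is always observed).
#' @param missing_rate Completely-at-random genotype missingness rate.
#' @param n_ancestry_dims Latent ancestry dimensions.
#' @param ancestry_strength Loading of the first ancestry dimension on the
#'   latent genotype scale and on ROI baselines (confounding strength).
#' @param apoe_freqs Named genotype-category frequencies for APOE
#'   (e2e2 ... e4e4), used for the CN group; e4-carrying categories are
#'   tilted upward in MCI/AD.
#' @param apoe_baseline_shift Baseline ROI shift per APOE e4 allele.
#' @param seed Global integer seed; all sub-generators derive their streams
#'   from it (genotypes, trajectories, missingness each use
#'   `seed + 1000003 * k` for fixed small k).
#' @return Object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_per_group = c(CN = 179, MCI = 296, AD = 157),
                       prevalence = c(CN = 0.875, MCI = 0.05, AD = 0.075),
                       n_snps = 300,
                       block_spec = default_block_spec(n_snps),
                       maf_range = c(0.05, 0.5),
                       n_causal = 10,
                       effect_size = -0.0015,
                       q_rois = 56,
                       visit_months = c(0, 6, 12, 18, 24),
                       variance_components = c(intercept = 0.04,
                                               slope = 1e-5,
                                               noise = 2.5e-3),
                       dropout_prob = 0.1,
                       missing_rate = 0.01,
                       n_ancestry_dims = 2,
                       ancestry_strength = 0.3,
                       apoe_freqs = c(e2e2 = 0.005, e2e3 = 0.06,
                                      e2e4 = 0.015, e3e3 = 0.62,
                                      e3e4 = 0.25, e4e4 = 0.05),
                       apoe_baseline_shift = -0.05,
                       seed = 1) {
  cfg <- list(n_per_group = n_per_group, prevalence = prevalence,
              n_snps = n_snps, block_spec = as.data.frame(block_spec),
              maf_range = maf_range, n_causal = n_causal,
              effect_size = effect_size, q_rois = q_rois,
              visit_months = visit_months,
              variance_components = variance_components,
              dropout_prob = dropout_prob, missing_rate = missing_rate,
              n_ancestry_dims = n_ancestry_dims,
              ancestry_strength = ancestry_strength,
              apoe_freqs = apoe_freqs,
              apoe_baseline_shift = apoe_baseline_shift,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$prevalence) - 1) > 1e-8) stop("prevalences must sum to 1")
  if (!all(c("CN", "MCI", "AD") %in% names(cfg$n_per_group)))
    stop("n_per_group must name CN, MCI, AD")
  if (sum(cfg$block_spec$size) != cfg$n_snps)
    stop("block sizes must sum to n_snps")
  if (any(cfg$block_spec$rho < 0 | cfg$block_spec$rho >= 1))
    stop("within-block correlation rho must be in [0, 1)")
  if (cfg$n_causal > cfg$n_snps) stop("n_causal must not exceed n_snps")
  if (cfg$maf_range[1] < 0.05 - 1e-12 || cfg$maf_range[2] > 0.5 + 1e-12)
    stop("maf_range must lie within [0.05, 0.5]")
  if (any(cfg$variance_components < 0) || cfg$variance_components["noise"] < 0)
    stop("variance components must be nonnegative")
  if (!0 %in% cfg$visit_months) stop("visit schedule must include baseline month 0")
  invisible(cfg)
}

#' Default LD-block layout inside the published linkage regions
#'
#' Splits `n_snps` into blocks of `block_size` (last block takes the
#' remainder) and rotates them through four of the autosomal linkage-region
#' bands, spacing SNPs 5 kb apart.
#'
#' @param n_snps Total SNP count.
#' @param block_size SNPs per block (default 10).
#' @param rho Within-block latent correlation (default 0.85).
#' @return Data frame `(region, chr, start_bp, end_bp, size, rho)`.
#' @export
default_block_spec <- function(n_snps, block_size = 10, rho = 0.85) {
  sizes <- rep(block_size, n_snps %/% block_size)
  if (n_snps %% block_size) sizes <- c(sizes, n_snps %% block_size)
  bands <- data.frame(
    region = c("1p31.1-q31.1", "6p21.1-q15", "10p14-q24", "19p13.3-qter"),
    chr = c(1, 6, 10, 19),
    start_mb = c(83, 43, 10, 8))
  k <- length(sizes)
  band_i <- rep_len(seq_len(nrow(bands)), k)
  offset <- stats::ave(seq_len(k), band_i, FUN = seq_along) - 1
  spacing <- 5000
  start <- bands$start_mb[band_i] * 1e6 + offset * 1e6
  data.frame(region = bands$region[band_i], chr = bands$chr[band_i],
             start_bp = start,
             end_bp = start + (sizes - 1) * spacing,
             size = sizes, rho = rho)
}

sub_seed <- function(seed, k) (as.integer(seed) + 1000003L * k) %% .Machine$integer.max

#' Simulate a genotype matrix with block LD structure
#'
#' Each SNP's genotype is produced by thresholding a latent Gaussian at the
#' Hardy-Weinberg quantiles of its minor-allele frequency (drawn uniformly
#' from `maf_range`), so the marginal genotype distribution is the binomial
#' HWE law. Within a block the latent variables share an exchangeable
#' correlation `rho`, which induces high pairwise genotype r-squared;
#' between blocks the latents are independent. The first ancestry dimension
#' shifts the latent mean of a random half of the SNPs, making allele
#' frequencies ancestry-dependent (the confounding the MDS adjustment is
#' meant to remove). Missing calls are injected completely at random.
#'
#' @param config A [sim_config()].
#' @param ancestry Optional subjects x dims matrix of latent ancestry
#'   coordinates; generated internally when NULL (as in
#'   [simulate_cohort()], which shares one draw across blocks).
#' @param n_subjects Number of subjects; default `sum(config$n_per_group)`.
#' @return A [genotype_matrix()] with region-labelled annotations, plus
#'   attributes `maf` (the generating frequencies) and `ancestry`.
#' @export
simulate_genotypes <- function(config, ancestry = NULL, n_subjects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- if (is.null(n_subjects)) sum(config$n_per_group) else n_subjects
  rng <- local_rng(sub_seed(config$seed, 1L))
  on.exit(rng())

  if (is.null(ancestry))
    ancestry <- matrix(stats::rnorm(n * config$n_ancestry_dims), n)
  bs <- config$block_spec
  p <- config$n_snps
  # SNPs in tight LD share their allele frequency: one MAF per block
  maf_block <- stats::runif(nrow(bs), config$maf_range[1], config$maf_range[2])
  maf <- rep(maf_block, bs$size)
  # ancestry acts at the block level (frequency gradients are locus-wide)
  block_loaded <- sample(c(TRUE, FALSE), nrow(bs), replace = TRUE)
  values <- matrix(NA_real_, n, p)
  ann <- vector("list", nrow(bs))
  col <- 0L
  bases <- c("A", "C", "G", "T")
  hwe_draw <- function(mk, shift) {
    z <- stats::rnorm(n) + shift
    q0 <- stats::qnorm((1 - mk)^2)
    q1 <- stats::qnorm((1 - mk)^2 + 2 * mk * (1 - mk))
    (z >= q0) + (z >= q1)
  }
  for (b in seq_len(nrow(bs))) {
    m <- bs$size[b]
    rho <- bs$rho[b]
    mk <- maf_block[b]
    shift <- if (block_loaded[b]) config$ancestry_strength * ancestry[, 1] else 0
    # allelic-copying LD model: each SNP copies a shared founder genotype
    # with probability rho^(1/4) per subject, otherwise redraws from the
    # same HWE law, so the pairwise genotype r^2 within the block is ~rho
    founder <- hwe_draw(mk, shift)
    copy_prob <- rho^(1 / 4)
    for (j in seq_len(m)) {
      k <- col + j
      own <- hwe_draw(mk, shift)
      take <- stats::runif(n) < copy_prob
      values[, k] <- ifelse(take, founder, own)
    }
    al <- sample(bases, 2)
    ann[[b]] <- data.frame(
      id = paste0("rs", b, "_", seq_len(m)),
      chr = bs$chr[b],
      bp = bs$start_bp[b] + (seq_len(m) - 1) *
        if (m > 1) (bs$end_bp[b] - bs$start_bp[b]) / (m - 1) else 0,
      minor = al[1], major = al[2],
      region = bs$region[b], block = b,
      stringsAsFactors = FALSE)
    col <- col + m
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * p) < config$missing_rate, n)
    values[miss] <- NA
  }
  g <- genotype_matrix(values, do.call(rbind, ann))
  attr(g, "maf") <- maf
  attr(g, "ancestry") <- ancestry
  g
}

#' Simulate a full longitudinal imaging-genetics cohort
#'
#' Generates genotypes (see [simulate_genotypes()]), diagnostic labels per
#' the configured (biased) group counts, APOE genotypes (e4-tilted in
#' MCI/AD), and per-ROI trajectories
#' `Y_ijt = b0j + b1j MCI + b2j AD + (b3j + b4j MCI + b5j AD + c_i) t
#'  + g1ij + g2ij t + e_ijt`,
#' where `c_i = sum_k effect_k * genotype_ik` over the causal SNPs, the
#' random intercept/slope pair is Gaussian with the configured variances,
#' and ancestry and APOE e4 dose shift the baselines (confounding). Causal
#' genotypes enter slopes with their missing entries mean-filled, so the
#' truth is well-defined for every subject.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_cohort"` with `genotypes`
#'   ([genotype_matrix()]), `phenotypes` (long data frame: subject_id, roi,
#'   month, value), `covariates` (subject_id, group, apoe), `truth` (causal
#'   ids/effects, group slope coefficients per ROI, per-subject random
#'   effects and true slopes) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- sum(config$n_per_group)
  q <- config$q_rois

  rng <- local_rng(sub_seed(config$seed, 2L))
  on.exit(rng())

  groups <- rep(c("CN", "MCI", "AD"),
                times = config$n_per_group[c("CN", "MCI", "AD")])
  ancestry <- matrix(stats::rnorm(n * config$n_ancestry_dims), n)

  # APOE: population frequencies for CN, e4 categories tilted up in MCI/AD
  apoe_levels <- names(config$apoe_freqs)
  e4_dose <- vapply(strsplit(apoe_levels, "e"), function(s)
    sum(s == "4"), numeric(1))
  apoe <- character(n)
  for (g in c("CN", "MCI", "AD")) {
    tilt <- c(CN = 0, MCI = 0.6, AD = 1.2)[g]
    f <- config$apoe_freqs * exp(tilt * e4_dose)
    idx <- which(groups == g)
    apoe[idx] <- sample(apoe_levels, length(idx), replace = TRUE,
                        prob = f / sum(f))
  }
  subj_e4 <- e4_dose[match(apoe, apoe_levels)]

  geno <- simulate_genotypes(config, ancestry = ancestry, n_subjects = n)

  # causal SNPs and per-subject slope contribution
  causal_idx <- if (config$n_causal > 0)
    sort(sample.int(config$n_snps, config$n_causal)) else integer(0)
  effects <- rep(config$effect_size, length(causal_idx))
  gfilled <- geno$values
  for (k in causal_idx) {
    kk <- gfilled[, k]
    gfilled[is.na(kk), k] <- mean(kk, na.rm = TRUE)
  }
  causal_contrib <- if (length(causal_idx))
    drop(gfilled[, causal_idx, drop = FALSE] %*% effects) else numeric(n)

  # ROI-level fixed effects: baseline thickness-like levels, group-ordered
  # atrophy slopes (AD fastest decline)
  beta <- data.frame(
    roi = paste0("roi", seq_len(q)),
    b0 = 2.5 + 0.3 * stats::rnorm(q),
    b1 = -0.02 + 0.01 * stats::rnorm(q),
    b2 = -0.05 + 0.01 * stats::rnorm(q),
    b3 = -0.0020 + 5e-4 * stats::rnorm(q),
    b4 = -0.0030 + 5e-4 * stats::rnorm(q),
    b5 = -0.0070 + 1e-3 * stats::rnorm(q))

  vc <- config$variance_components
  months <- config$visit_months
  mci <- as.numeric(groups == "MCI")
  ad <- as.numeric(groups == "AD")

  g1 <- matrix(stats::rnorm(n * q, sd = sqrt(vc["intercept"])), n)
  g2 <- matrix(stats::rnorm(n * q, sd = sqrt(vc["slope"])), n)

  subject_id <- paste0("S", seq_len(n))
  recs <- vector("list", q)
  true_slope <- matrix(0, n, q, dimnames = list(subject_id, beta$roi))
  base_shift <- config$ancestry_strength * 0.2 * ancestry[, 1] +
    config$apoe_baseline_shift * subj_e4
  for (j in seq_len(q)) {
    slope_j <- beta$b3[j] + beta$b4[j] * mci + beta$b5[j] * ad +
      causal_contrib + g2[, j]
    true_slope[, j] <- slope_j
    level0 <- beta$b0[j] + beta$b1[j] * mci + beta$b2[j] * ad +
      base_shift + g1[, j]
    Yj <- outer(level0, rep(1, length(months))) +
      outer(slope_j, months) +
      matrix(stats::rnorm(n * length(months), sd = sqrt(vc["noise"])), n)
    recs[[j]] <- data.frame(
      subject_id = rep(subject_id, length(months)),
      roi = beta$roi[j],
      month = rep(months, each = n),
      value = as.vector(Yj),
      stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, recs)

  if (config$dropout_prob > 0) {
    fup <- pheno$month > 0
    drop_rec <- fup & stats::runif(nrow(pheno)) < config$dropout_prob
    # never drop a subject's last follow-up for an ROI: the longitudinal
    # table guarantees a baseline plus at least one follow-up per subject
    key <- paste(pheno$subject_id, pheno$roi)
    lost <- tapply(drop_rec[fup], key[fup], all)
    for (k in names(lost)[lost]) {
      i <- which(key == k & fup)
      drop_rec[i[1]] <- FALSE
    }
    pheno <- pheno[!drop_rec, ]
  }

  truth <- list(
    causal_snp_ids = geno$snps$id[causal_idx],
    causal_effects = effects,
    group_slopes = beta,
    random_intercepts = g1,
    random_slopes = g2,
    true_slopes = true_slope,
    ancestry = ancestry)

  covariates <- data.frame(subject_id = subject_id, group = groups,
                           apoe = apoe, stringsAsFactors = FALSE)
  structure(list(genotypes = geno, phenotypes = pheno,
                 covariates = covariates, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (CN %d / MCI %d / AD %d), %d SNPs, %d ROIs\n",
              nrow(x$covariates),
              sum(x$covariates$group == "CN"),
              sum(x$covariates$group == "MCI"),
              sum(x$covariates$group == "AD"),
              ncol(x$genotypes$values), x$config$q_rois))
  cat(sprintf("  %d causal SNPs, effect %g per allele per month; seed %d\n",
              length(x$truth$causal_snp_ids), x$config$effect_size,
              x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes PLINK-text genotypes (`cohort.ped` / `cohort.map`, whitespace
#' delimited, missing calls as `0 0`), a SNP annotation table
#' (`snp_info.csv`, carrying minor/major alleles and region labels), the
#' long-format phenotype table (`phenotypes.csv`), the covariate table
#' (`covariates.csv`) and the ground-truth record (`truth.json`). The file
#' set round-trips losslessly through [read_cohort()].
#'
#' @param cohort A `"sim_cohort"` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  write_ped(cohort$genotypes, file.path(out_dir, "cohort"))
  utils::write.csv(cohort$genotypes$snps,
                   file.path(out_dir, "snp_info.csv"), row.names = FALSE)
  utils::write.csv(cohort$phenotypes, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(causal_snp_ids = truth$causal_snp_ids,
         causal_effects = truth$causal_effects,
         group_slopes = truth$group_slopes,
         seed = cohort$config$seed),
    file.path(out_dir, "truth.json"), digits = NA, auto_unbox = FALSE)
  invisible(file.path(out_dir, c("cohort.ped", "cohort.map", "snp_info.csv",
                                 "phenotypes.csv", "covariates.csv",
                                 "truth.json")))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the file set.
#' @return List with `genotypes`, `phenotypes`, `covariates`, `truth`.
#' @export
read_cohort <- function(dir) {
  snp_info <- utils::read.csv(file.path(dir, "snp_info.csv"),
                              stringsAsFactors = FALSE)
  geno <- read_ped(file.path(dir, "cohort.ped"),
                   file.path(dir, "cohort.map"),
                   minor_alleles = stats::setNames(snp_info$minor, snp_info$id))
  geno$snps <- snp_info
  dimnames(geno$values) <- list(geno$subject_ids, snp_info$id)
  list(genotypes = geno,
       phenotypes = utils::read.csv(file.path(dir, "phenotypes.csv"),
                                    stringsAsFactors = FALSE),
       covariates = utils::read.csv(file.path(dir, "covariates.csv"),
                                    stringsAsFactors = FALSE),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
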