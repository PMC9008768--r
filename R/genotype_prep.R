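#' Construct a genotype matrix of minor-allele counts
#'
#' The central genomic container: a subjects x SNPs matrix of minor-allele
#' counts in \{0, 1, 2\} (NA = missing), with per-SNP annotations.
#'
#' @param values Numeric/integer matrix, subjects in rows, SNPs in columns.
#'   Entries must be 0, 1, 2 or NA.
#' @param snps Data frame with one row per SNP: columns `id`, `chr`
#'   (chromosome, 1-22 or "X"/"Y"), `bp` (1-based physical position), and
#'   optionally `minor`, `major` (allele letters) and `region` (linkage
#'   region label).
#' @param subject_ids Optional character vector of subject identifiers;
#'   defaults to rownames of `values` or `S1..Sn`.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(values, snps, subject_ids = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1, 2) | is.na(values)))
    stop("genotype values must be in {0, 1, 2} or NA")
  snps <- as.data.frame(snps)
  if (!all(c("id", "chr", "bp") %in% names(snps)))
    stop("'snps' needs columns id, chr, bp")
  if (nrow(snps) != ncol(values))
    stop("one annotation row per SNP column required")
  if (anyDuplicated(snps$id)) stop("SNP ids must be unique")
  if (any(snps$bp <= 0)) stop("bp positions must be positive")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  dimnames(values) <- list(subject_ids, snps$id)
  if (is.null(snps$region)) snps$region <- NA_character_
  structure(list(values = values, snps = snps, subject_ids = subject_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  if (any(!is.na(x$snps$region)))
    cat("  linkage regions:",
        paste(unique(stats::na.omit(x$snps$region)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

# subset SNP columns, keeping annotations aligned
subset_snps <- function(g, keep) {
  genotype_matrix(g$values[, keep, drop = FALSE],
                  g$snps[keep, , drop = FALSE],
                  g$subject_ids)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed minor-allele count, enumerate
#' all possible heterozygote counts (which share the allele count's parity),
#' compute their conditional probabilities, and sum the probabilities of all
#' tables no more probable than the observed one (two-sided by probability
#' ordering).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts: major homozygote, heterozygote,
#'   minor homozygote.
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_pvalue(1, 2, 1)  # observed table is modal: p = 1
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_minor <- 2 * n_aa + n_Aa            # minor allele count
  # possible heterozygote counts share parity with the allele count
  het_max <- min(n_minor, 2 * n - n_minor)
  hets <- seq(n_minor %% 2, het_max, by = 2)
  # log P(n_Aa = h | allele counts) up to a constant:
  #   2^h * n! / (nAA! nAa! naa!) with nAA, naa implied by h
  logp <- vapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    AA <- n - aa - h
    h * log(2) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hets == n_Aa]
  min(1, sum(p[p <= p_obs + 1e-12]))
}

#' Genotype quality-control filter
#'
#' Drops SNPs in the fixed order: call rate, then minor allele frequency,
#' then Hardy-Weinberg equilibrium (exact test, by default in all retained
#' subjects). Sex-chromosome SNPs are removed first as part of the marker
#' restriction phase.
#'
#' @param g A [genotype_matrix()].
#' @param call_rate_min Minimum genotyping call rate (default 0.95).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_alpha Hardy-Weinberg exact-test significance threshold
#'   (default 1e-6).
#' @param hwe_subjects Optional subject-id subset in which to test HWE (e.g.
#'   controls only); default all subjects.
#' @param drop_sex_chromosomes Drop SNPs on X/Y (default TRUE).
#' @return List with `genotypes` (the filtered matrix) and `report`, a data
#'   frame of SNPs dropped per filter in application order.
#' @export
qc_filter <- function(g, call_rate_min = 0.95, maf_min = 0.05,
                      hwe_alpha = 1e-6, hwe_subjects = NULL,
                      drop_sex_chromosomes = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$values
  n_start <- ncol(v)
  keep <- rep(TRUE, n_start)

  dropped_sex <- 0L
  if (drop_sex_chromosomes) {
    sex <- as.character(g$snps$chr) %in% c("X", "Y", "23", "24", "25")
    dropped_sex <- sum(sex & keep)
    keep <- keep & !sex
  }

  call_rate <- colMeans(!is.na(v))
  fail_cr <- keep & call_rate < call_rate_min
  keep <- keep & !fail_cr

  maf <- col_maf(v)
  fail_maf <- keep & (is.na(maf) | maf < maf_min)
  keep <- keep & !fail_maf

  hwe_rows <- if (is.null(hwe_subjects)) seq_len(nrow(v)) else
    match(hwe_subjects, g$subject_ids)
  fail_hwe <- rep(FALSE, n_start)
  for (k in which(keep)) {
    gk <- v[hwe_rows, k]
    gk <- gk[!is.na(gk)]
    p <- hwe_exact_pvalue(sum(gk == 0), sum(gk == 1), sum(gk == 2))
    fail_hwe[k] <- p < hwe_alpha
  }
  keep <- keep & !fail_hwe

  if (!any(keep)) stop("all SNPs removed by quality control")
  report <- data.frame(
    filter = c("sex_chromosome", "call_rate", "maf", "hwe"),
    threshold = c(NA, call_rate_min, maf_min, hwe_alpha),
    dropped = c(dropped_sex, sum(fail_cr), sum(fail_maf), sum(fail_hwe)))
  list(genotypes = subset_snps(g, keep), report = report)
}

# minor allele frequency per column; NA if no non-missing calls.
# values are minor-allele counts so MAF is simply the mean count / 2,
# folded to [0, 0.5] in case coding drifted.
col_maf <- function(v) {
  f <- colMeans(v, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Restrict a genotype matrix to autosomal linkage regions
#'
#' Keeps SNPs whose position falls inside one of the listed regions
#' (closed intervals on the Mb scale, 1-based bp) and attaches the region
#' label. Non-autosomal SNPs are dropped: the region table is autosomal.
#'
#' @param g A [genotype_matrix()].
#' @param regions Data frame with columns `chr`, `band`, `start_mb`,
#'   `end_mb`, e.g. from [read_region_table()].
#' @return A [genotype_matrix()] restricted to in-region SNPs, with the
#'   `region` annotation set to "chr band".
#' @export
restrict_to_regions <- function(g, regions) {
  stopifnot(inherits(g, "genotype_matrix"))
  regions <- as.data.frame(regions)
  if (!all(c("chr", "start_mb", "end_mb") %in% names(regions)))
    stop("'regions' needs columns chr, start_mb, end_mb")
  if (any(regions$start_mb >= regions$end_mb)) stop("region start must precede end")
  chr <- suppressWarnings(as.integer(as.character(g$snps$chr)))
  label <- rep(NA_character_, nrow(g$snps))
  for (r in seq_len(nrow(regions))) {
    hit <- !is.na(chr) & chr == regions$chr[r] &
      g$snps$bp >= regions$start_mb[r] * 1e6 &
      g$snps$bp <= regions$end_mb[r] * 1e6
    label[hit] <- paste0(regions$chr[r],
                         if (!is.null(regions$band)) regions$band[r] else "")
  }
  out <- subset_snps(g, !is.na(label))
  out$snps$region <- label[!is.na(label)]
  out
}

#' Read a linkage-region table
#'
#' CSV with columns `chr`, `band`, `start_mb`, `end_mb` (closed Mb
#' intervals). The package ships the published Alzheimer's-disease linkage
#' regions in `system.file("extdata", "alzgene_linkage_regions.csv",
#' package = "rvscca")`.
#'
#' @param path CSV path.
#' @return Data frame of regions.
#' @export
read_region_table <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("chr", "start_mb", "end_mb") %in% names(reg)))
    stop("region table needs columns chr, start_mb, end_mb")
  reg
}

#' Fill sporadically missing genotypes
#'
#' Replaces each missing entry by the SNP's rounded within-sample mean
#' minor-allele count. Intended for data that already passed the call-rate
#' filter, where missingness is sparse.
#'
#' @param g A [genotype_matrix()].
#' @return A [genotype_matrix()] with no missing entries.
#' @export
fill_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$values
  nmiss <- colSums(is.na(v))
  if (any(nmiss == nrow(v)))
    stop("SNP(s) with all entries missing; run qc_filter first")
  for (k in which(nmiss > 0)) {
    v[is.na(v[, k]), k] <- round_half_away(mean(v[, k], na.rm = TRUE))
  }
  genotype_matrix(v, g$snps, g$subject_ids)
}

#' Identity-by-state distance matrix
#'
#' `D[i, j] = 1 - (1 / (2 m)) * sum_k (2 - |g_ik - g_jk|)` over the m SNPs:
#' the complement of the average fraction of shared alleles. Values in
#' \[0, 1\], zero diagonal, symmetric.
#'
#' @param g A [genotype_matrix()] without missing values.
#' @return Symmetric subjects x subjects matrix of IBS distances.
#' @export
ibs_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$values
  if (anyNA(v)) stop("fill missing genotypes before computing IBS distances")
  m <- ncol(v)
  if (m == 0) stop("no SNPs")
  # sum_k |g_ik - g_jk| via indicator cross-products per genotype value
  A0 <- (v == 0) * 1; A1 <- (v == 1) * 1; A2 <- (v == 2) * 1
  diff1 <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1)
  diff2 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  D <- (diff1 + 2 * diff2) / (2 * m)
  dimnames(D) <- list(g$subject_ids, g$subject_ids)
  diag(D) <- 0
  D
}

#' Ancestry coordinates by classical multidimensional scaling
#'
#' Torgerson MDS of a distance matrix: double-center `-D^2 / 2`, take the
#' top-d eigenvectors scaled by the square root of their eigenvalues. The
#' eigenvector sign is fixed so each column's largest-magnitude loading is
#' positive. Used on the IBS distance matrix to obtain principal coordinates
#' that proxy population structure.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param d Number of coordinate dimensions (default 10).
#' @return Object of class `"ancestry_coords"`: list with `coords`
#'   (subjects x d), `eig` (all eigenvalues) and `positive_mass_captured`
#'   (fraction of the positive eigenvalue mass in the top d).
#' @export
mds_coordinates <- function(D, d = 10) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("'D' must be symmetric")
  n <- nrow(D)
  mds <- suppressWarnings(stats::cmdscale(D, k = min(d, n - 1), eig = TRUE))
  eig <- mds$eig
  X <- mds$points
  if (is.null(X) || ncol(X) == 0) X <- matrix(0, n, 0)
  n_pos <- ncol(X)
  if (n_pos < d) {
    warning("requested ", d, " dimensions but configuration has rank ", n_pos,
            "; padding with zero columns")
    X <- cbind(X, matrix(0, n, d - n_pos))
  }
  # sign convention: largest |loading| positive
  for (k in seq_len(ncol(X))) {
    if (any(X[, k] != 0)) {
      i <- which.max(abs(X[, k]))
      if (X[i, k] < 0) X[, k] <- -X[, k]
    }
  }
  colnames(X) <- paste0("MDS", seq_len(ncol(X)))
  rownames(X) <- rownames(D)
  pos <- eig[eig > 0]
  frac <- if (length(pos)) sum(pos[seq_len(min(d, length(pos)))]) / sum(pos) else 0
  structure(list(coords = X, eig = eig, positive_mass_captured = frac),
            class = "ancestry_coords")
}

#' @export
print.ancestry_coords <- function(x, ...) {
  cat(sprintf("Ancestry coordinates: %d subjects x %d dimensions (%.1f%% of positive eigenvalue mass)\n",
              nrow(x$coords), ncol(x$coords), 100 * x$positive_mass_captured))
  invisible(x)
}

#' Pairwise linkage disequilibrium as squared Pearson correlation
#'
#' @param g A [genotype_matrix()] without missing values.
#' @param i,j SNP ids (or column indices).
#' @param subjects Optional subject-id subset on which to evaluate (e.g.
#'   cognitively normal subjects only); default all.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(g, i, j, subjects = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  rows <- if (is.null(subjects)) seq_len(nrow(g$values)) else
    match(subjects, g$subject_ids)
  xi <- g$values[rows, i]
  xj <- g$values[rows, j]
  if (stats::var(xi) == 0 || stats::var(xj) == 0)
    stop("monomorphic SNP in the evaluation subset: r^2 undefined")
  stats::cor(xi, xj)^2
}

#' Group SNPs into linkage-disequilibrium blocks
#'
#' A block is a set of SNPs in which every pair has r-squared above the
#' threshold. Blocks are built greedily and deterministically: seed with the
#' left-most (by position) unassigned SNP, then walk right, adding a SNP only
#' if its r-squared with every current member exceeds the threshold.
#' Singleton SNPs are left unlabelled (NA).
#'
#' @param g A [genotype_matrix()] without missing values.
#' @param snp_subset SNP ids to group (default: all SNPs in `g`).
#' @param r2_min Pairwise r-squared threshold (default 0.7).
#' @param subjects Optional subject subset for the r-squared evaluation.
#' @return Data frame `(id, chr, bp, block)` sorted by chromosome and
#'   position; `block` is an integer label or NA for singletons.
#' @export
ld_blocks <- function(g, snp_subset = NULL, r2_min = 0.7, subjects = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(snp_subset)) snp_subset <- g$snps$id
  ann <- g$snps[match(snp_subset, g$snps$id), ]
  ord <- order(suppressWarnings(as.integer(as.character(ann$chr))), ann$bp)
  ann <- ann[ord, ]
  ids <- ann$id
  p <- length(ids)
  block <- rep(NA_integer_, p)
  next_block <- 1L
  assigned <- rep(FALSE, p)
  for (s in seq_len(p)) {
    if (assigned[s]) next
    members <- s
    for (t in seq_len(p)) {
      if (t <= s || assigned[t]) next
      if (as.character(ann$chr[t]) != as.character(ann$chr[s])) next
      ok <- all(vapply(members, function(m)
        ld_r2(g, ids[m], ids[t], subjects = subjects) > r2_min, logical(1)))
      if (ok) members <- c(members, t)
    }
    if (length(members) > 1) {
      block[members] <- next_block
      next_block <- next_block + 1L
      assigned[members] <- TRUE
    } else assigned[s] <- TRUE
  }
  data.frame(id = ids, chr = ann$chr, bp = ann$bp, block = block,
             row.names = NULL, stringsAsFactors = FALSE)
}
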