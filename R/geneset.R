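#' Map SNPs to genes with padding
#'
#' A SNP is assigned to a gene when its position falls within
#' `[start - padding, end + padding]` on the same chromosome (1-based,
#' closed intervals); assignment is many-to-many.
#'
#' @param genes Data frame with `gene_id`, `chr`, `start`, `end` (bp).
#' @param snps Data frame with `id`, `chr`, `bp`.
#' @param padding Bp padding around each gene (default 20,000).
#' @return Data frame `(gene_id, snp_id)`, one row per assignment.
#' @export
gene_map <- function(genes, snps, padding = 20000) {
  genes <- as.data.frame(genes)
  if (any(genes$start > genes$end)) stop("gene start must not exceed end")
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- as.character(snps$chr) == as.character(genes$chr[i]) &
      snps$bp >= genes$start[i] - padding &
      snps$bp <= genes$end[i] + padding
    if (!any(hit)) return(NULL)
    data.frame(gene_id = genes$gene_id[i], snp_id = snps$id[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(gene_id = character(), snp_id = character())
  else out
}

#' Gene-level summaries of variable exclusion probabilities
#'
#' The gene score is the second-smallest VEP among the gene's SNPs, a guard
#' against spuriously strong signal from single SNPs in long genes. Genes
#' with a single mapped SNP fall back to that SNP's VEP (flagged); genes
#' with no mapped SNPs are excluded.
#'
#' @param vep Named numeric vector of per-SNP variable exclusion
#'   probabilities (names = SNP ids), e.g. the `vep` column of a
#'   [bootstrap_vip()] table.
#' @param map Assignment table from [gene_map()].
#' @return Data frame `(gene_id, n_snps, score, single_snp)`.
#' @export
gene_scores <- function(vep, map) {
  if (is.null(names(vep))) stop("'vep' must be named by SNP id")
  map <- map[map$snp_id %in% names(vep), , drop = FALSE]
  if (!nrow(map)) stop("no mapped SNPs with VEP values")
  by_gene <- split(vep[map$snp_id], map$gene_id)
  out <- data.frame(
    gene_id = names(by_gene),
    n_snps = vapply(by_gene, length, integer(1)),
    score = vapply(by_gene, function(v)
      if (length(v) >= 2) sort(v)[2] else v[1], numeric(1)),
    single_snp = vapply(by_gene, length, integer(1)) == 1,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Transform VEP gene scores to z-scores
#'
#' `z = -qnorm(vep)` after clipping to `[1/(2B), 1 - 1/(2B)]` (B = number
#' of bootstrap replicates), so strong inclusion evidence (small VEP) maps
#' to large positive z. Used as the per-gene score for the maxmean
#' statistic.
#'
#' @param score Numeric VEP-scale scores in \[0, 1\].
#' @param B Bootstrap replicate count used to produce the VEPs.
#' @return Numeric z-scores.
#' @export
vep_to_z <- function(score, B) {
  eps <- 1 / (2 * B)
  -stats::qnorm(pmin(pmax(score, eps), 1 - eps))
}

#' Maxmean gene-set statistic
#'
#' For gene z-scores in a set, `maxmean = max(mean(z+), mean(z-))` where
#' `z+ = max(z, 0)`, `z- = max(-z, 0)` and both means divide by the set
#' size: the larger of the average positive and average negative parts,
#' robust to a few outlying genes.
#'
#' @param z Numeric z-scores of the set members.
#' @return The maxmean value.
#' @export
maxmean_stat <- function(z) {
  if (!length(z)) stop("empty gene set")
  max(mean(pmax(z, 0)), mean(pmax(-z, 0)))
}

#' Restandardized maxmean statistic for one gene set
#'
#' Computes the maxmean statistic of the member genes and restandardizes it
#' by the mean and standard deviation of the statistic over reference sets
#' of the same size: either `n_random` random gene draws from the scored
#' universe (default, the resampling form) or the individual-gene
#' asymptotic moments (`reference = "all"`).
#'
#' @param scores Gene score table from [gene_scores()] (or a named numeric
#'   z vector).
#' @param set_genes Character vector of member gene ids.
#' @param B Bootstrap count for the VEP -> z transform (ignored when
#'   `scores` is already numeric z).
#' @param reference `"random"` or `"all"`.
#' @param n_random Random reference sets (default 200).
#' @param seed Seed for the random reference draws.
#' @return List with `maxmean`, `restandardized`, `n_genes`.
#' @export
maxmean_set_statistic <- function(scores, set_genes, B = 1000,
                                  reference = c("random", "all"),
                                  n_random = 200, seed = 1) {
  reference <- match.arg(reference)
  if (is.data.frame(scores)) {
    z <- vep_to_z(scores$score, B)
    names(z) <- scores$gene_id
  } else z <- scores
  # center/scale across the gene universe
  z <- (z - mean(z)) / stats::sd(z)
  members <- intersect(set_genes, names(z))
  if (!length(members)) stop("no scored genes in the set")
  obs <- maxmean_stat(z[members])
  m <- length(members)
  if (m >= length(z)) {
    warning("set covers the whole gene universe; restandardization degenerate")
    return(list(maxmean = obs, restandardized = NA_real_, n_genes = m))
  }
  if (reference == "random") {
    rng <- local_rng(seed)
    null <- vapply(seq_len(n_random), function(i)
      maxmean_stat(z[sample.int(length(z), m)]), numeric(1))
    rng()
    mu <- mean(null); sdv <- stats::sd(null)
  } else {
    # individual-gene moments of max(mean z+, mean z-) at size m via the
    # normal-theory approximation used in restandardized gene-set tests
    singles <- vapply(seq_along(z), function(i) maxmean_stat(z[i]), numeric(1))
    mu <- mean(singles); sdv <- stats::sd(singles) / sqrt(m)
  }
  if (!is.finite(sdv) || sdv == 0) {
    warning("restandardization reference has zero spread")
    return(list(maxmean = obs, restandardized = NA_real_, n_genes = m))
  }
  list(maxmean = obs, restandardized = (obs - mu) / sdv, n_genes = m)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Permutation gene-set enrichment test on exclusion probabilities
#'
#' Observed set statistics come from the supplied VEPs; the null reference
#' is built by re-running the SNP-refinement under row permutation of the
#' phenotype block (`refit_fun`), recomputing gene scores and restandardized
#' maxmean statistics each time. Empirical p-values use the add-one
#' estimator and are Benjamini-Hochberg adjusted; candidate sets are those
#' with adjusted p at or below the (deliberately liberal) FDR cut.
#'
#' @param vep Named per-SNP VEP vector (observed).
#' @param map Gene assignment table from [gene_map()].
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param refit_fun Function `(perm_seed) -> named VEP vector` that redoes
#'   the bootstrap-VIP refinement with phenotype rows permuted; see
#'   [make_vep_refitter()].
#' @param B Bootstrap count behind the VEPs (for the z transform).
#' @param n_perm Number of permutation samples (default 100).
#' @param fdr_cut BH-adjusted p threshold for candidates (default 0.8).
#' @param seed Master seed.
#' @param reference Restandardization reference (see
#'   [maxmean_set_statistic()]).
#' @return Object of class `"geneset_result"`: data frame per set with
#'   `maxmean`, `restandardized`, `p_value`, `p_adjusted`, `candidate`.
#' @export
geneset_permutation <- function(vep, map, sets, refit_fun, B = 1000,
                                n_perm = 100, fdr_cut = 0.8, seed = 1,
                                reference = "random") {
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  set_stat <- function(v) {
    gs <- gene_scores(v, map)
    vapply(names(sets), function(s)
      maxmean_set_statistic(gs, sets[[s]], B = B, reference = reference,
                            seed = seed)$restandardized, numeric(1))
  }
  obs <- set_stat(vep)
  null <- matrix(NA_real_, n_perm, length(sets))
  for (b in seq_len(n_perm)) {
    null[b, ] <- set_stat(refit_fun(sub_seed(seed, 10L + b)))
  }
  p <- vapply(seq_along(sets), function(s)
    (1 + sum(null[, s] >= obs[s], na.rm = TRUE)) / (1 + n_perm), numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(set = names(sets),
                    maxmean = vapply(names(sets), function(s)
                      maxmean_set_statistic(gene_scores(vep, map), sets[[s]],
                                            B = B, reference = reference,
                                            seed = seed)$maxmean, numeric(1)),
                    restandardized = obs,
                    p_value = p, p_adjusted = padj,
                    candidate = padj <= fdr_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("geneset_result", "data.frame"),
            n_perm = n_perm, fdr_cut = fdr_cut, seed = seed)
}

#' Build a permutation refitter for the gene-set null
#'
#' Returns a closure that permutes the phenotype rows (together with their
#' sampling weights), reruns [bootstrap_vip()] at the fixed penalty with a
#' scaled-down replicate count, and returns the null VEP vector.
#'
#' @param X,Y Adjusted data matrices.
#' @param w Per-subject weights.
#' @param groups Diagnostic labels for the stratified bootstrap.
#' @param lambda_u Fixed penalty.
#' @param B Bootstrap replicates per permutation (keep small; this runs
#'   once per permutation sample).
#' @return Function `(perm_seed) -> named VEP vector`.
#' @export
make_vep_refitter <- function(X, Y, w, groups, lambda_u, B = 50) {
  force(X); force(Y); force(w); force(groups); force(lambda_u); force(B)
  function(perm_seed) {
    rng <- local_rng(perm_seed)
    idx <- sample.int(nrow(Y))
    rng()
    vt <- bootstrap_vip(X, Y[idx, , drop = FALSE], w[idx], groups,
                        lambda_u = lambda_u, B = B, seed = perm_seed)
    stats::setNames(vt$vep, vt$id)
  }
}
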