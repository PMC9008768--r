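APOE_LEVELS <- c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")

#' Build the confounder design matrix
#'
#' Intercept, ancestry principal coordinates, and dummy variables for the
#' APOE genotype categories present (reference category: the most frequent
#' genotype, unless supplied). Constant coordinate columns are dropped with
#' a warning so the design has full column rank.
#'
#' @param covariates Data frame with `subject_id` and `apoe` columns.
#' @param coords An `"ancestry_coords"` object or a subjects x d coordinate
#'   matrix, rows aligned with `covariates`.
#' @param apoe_reference Reference APOE category; default the most frequent.
#' @return Numeric design matrix (subjects x columns) with attribute
#'   `"apoe_reference"`.
#' @export
build_design <- function(covariates, coords, apoe_reference = NULL) {
  if (inherits(coords, "ancestry_coords")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(covariates))
    stop("one coordinate row per subject required")
  apoe <- as.character(covariates$apoe)
  bad <- setdiff(unique(apoe), APOE_LEVELS)
  if (length(bad))
    stop("unknown APOE code(s): ", paste(bad, collapse = ", "))
  if (is.null(apoe_reference))
    apoe_reference <- names(which.max(table(apoe)))

  constant <- apply(coords, 2, function(x) stats::var(x) == 0)
  if (any(constant)) {
    warning("dropping constant coordinate column(s): ",
            paste(colnames(coords)[constant], collapse = ", "))
    coords <- coords[, !constant, drop = FALSE]
  }
  cats <- setdiff(sort(unique(apoe)), apoe_reference)
  dummies <- vapply(cats, function(cc) as.numeric(apoe == cc),
                    numeric(length(apoe)))
  if (length(cats) == 0) dummies <- matrix(0, length(apoe), 0)
  D <- cbind(`(Intercept)` = 1, coords, dummies)
  colnames(D) <- c("(Intercept)", colnames(coords), paste0("apoe_", cats))
  attr(D, "apoe_reference") <- apoe_reference
  D
}

#' Residualize a matrix on a design by weighted ordinary least squares
#'
#' Per column m of M, computes the weighted least-squares fit
#' `min_beta sum_i w_i (m_i - D_i beta)^2` and returns the residual
#' `m - D beta_hat`. The residuals satisfy the weighted orthogonality
#' `t(D) %*% (w * r) = 0`.
#'
#' @param M Subjects x k numeric matrix (e.g. minor-allele counts or
#'   predicted rates).
#' @param design Design matrix from [build_design()].
#' @param w Positive per-subject weights.
#' @return Residual matrix of the same shape as M.
#' @export
weighted_residualize <- function(M, design, w) {
  M <- as.matrix(M)
  design <- as.matrix(design)
  if (nrow(M) != nrow(design)) stop("rows of M and design must align")
  if (length(w) != nrow(M)) stop("one weight per subject required")
  if (any(w <= 0)) stop("weights must be positive")
  sw <- sqrt(w)
  Dw <- design * sw
  qrD <- qr(Dw)
  if (qrD$rank < ncol(design))
    stop("design matrix is rank deficient after repair")
  beta <- qr.coef(qrD, M * sw)
  M - design %*% beta
}

#' Assemble the adjusted analysis matrices X and Y
#'
#' End-to-end confounder adjustment: builds the design (intercept + ancestry
#' coordinates + APOE dummies), residualizes the minor-allele counts and the
#' predicted rates on it by weighted OLS, and (by default) standardizes the
#' residual columns to weighted mean 0 / weighted variance 1 so the sparse
#' CCA operates on a cross-correlation matrix. Zero-variance residual
#' columns are dropped with a warning.
#'
#' @param geno A [genotype_matrix()] with no missing values (rows must
#'   align with `covariates`).
#' @param rates Subjects x ROIs rate matrix from [predict_rates()].
#' @param coords Ancestry coordinates (see [build_design()]).
#' @param covariates Data frame with `subject_id`, `group`, `apoe`.
#' @param weights A `"weight_vector"` from [compute_weights()], or a
#'   numeric per-subject weight vector.
#' @param standardize Standardize residual columns (default TRUE).
#' @return Object of class `"weighted_cohort"`: list with `X` (adjusted
#'   genotypes), `Y` (adjusted rates), `w`, `groups`, `snp_ids`, `roi_ids`.
#' @export
adjust_cohort <- function(geno, rates, coords, covariates, weights,
                          standardize = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (anyNA(geno$values)) stop("fill missing genotypes before adjustment")
  rates <- as.matrix(rates)
  subjects <- covariates$subject_id
  if (!identical(rownames(rates), subjects))
    rates <- rates[match(subjects, rownames(rates)), , drop = FALSE]
  gv <- geno$values[match(subjects, geno$subject_ids), , drop = FALSE]
  w <- if (inherits(weights, "weight_vector"))
    subject_weights(weights, covariates$group) else as.numeric(weights)

  D <- build_design(covariates, coords)
  X <- weighted_residualize(gv, D, w)
  Y <- weighted_residualize(rates, D, w)
  if (standardize) {
    Xs <- standardize_weighted(X, w)
    Ys <- standardize_weighted(Y, w)
    if (any(Xs$zero))
      warning(sum(Xs$zero), " zero-variance genotype column(s) dropped")
    if (any(Ys$zero))
      warning(sum(Ys$zero), " zero-variance rate column(s) dropped")
    X <- Xs$m[, !Xs$zero, drop = FALSE]
    Y <- Ys$m[, !Ys$zero, drop = FALSE]
  }
  structure(list(X = X, Y = Y, w = w, groups = covariates$group,
                 snp_ids = colnames(X), roi_ids = colnames(Y)),
            class = "weighted_cohort")
}

#' @export
print.weighted_cohort <- function(x, ...) {
  cat(sprintf("Adjusted cohort: %d subjects, %d SNP columns, %d ROI columns\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  cat(sprintf("  weights: sum %.4g over %d subjects\n", sum(x$w), length(x$w)))
  invisible(x)
}
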