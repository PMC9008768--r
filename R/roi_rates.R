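#' Fit the per-ROI linear mixed model for rates of change
#'
#' For one region of interest, fits
#' `Y_it = b0 + b1 MCI + b2 AD + b3 t + b4 MCI t + b5 AD t + g1_i + g2_i t + e_it`
#' by REML with an unstructured 2x2 random-effects covariance (lme4
#' default). MCI/AD are standard 0/1 dummies with CN the reference group.
#' The conditional modes (empirical BLUPs) of the subject-specific slope
#' deviations `g2_i` are extracted for rate prediction. Singular fits (e.g.
#' zero slope variance) are flagged but still return conditional modes;
#' non-convergent REML fits fall back to ML and then to a
#' random-intercept-only model, flagged.
#'
#' @param data Long-format data frame with columns `subject_id`, `roi`,
#'   `month`, `value`.
#' @param roi The ROI identifier to fit.
#' @param groups Named character vector: subject_id -> group (CN/MCI/AD).
#' @return Object of class `"roi_lmm"`: list with `roi`, `beta` (named
#'   b0..b5), `varcor` (var(g1), var(g2), cov, sigma2), `gamma2` (named
#'   conditional modes), `gamma1`, `singular`, `converged`, `fallback`,
#'   `n_subjects`.
#' @export
fit_roi_lmm <- function(data, roi, groups) {
  d <- data[data$roi == roi, , drop = FALSE]
  if (!nrow(d)) stop("no records for ROI ", roi)
  d$group <- groups[as.character(d$subject_id)]
  if (anyNA(d$group)) stop("group label missing for some subjects")
  per_subj <- table(d$subject_id)
  if (any(per_subj < 2))
    stop("every subject needs at least two time points for ROI ", roi)
  d$mci <- as.numeric(d$group == "MCI")
  d$ad <- as.numeric(d$group == "AD")

  fallback <- "none"
  fit <- suppressWarnings(suppressMessages(try(
    lme4::lmer(value ~ mci + ad + month + mci:month + ad:month +
                 (1 + month | subject_id),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    silent = TRUE)))
  conv_ok <- function(f) !inherits(f, "try-error") &&
    length(f@optinfo$conv$lme4) == 0
  if (!conv_ok(fit)) {
    f2 <- suppressWarnings(suppressMessages(try(
      lme4::lmer(value ~ mci + ad + month + mci:month + ad:month +
                   (1 + month | subject_id),
                 data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
      silent = TRUE)))
    if (conv_ok(f2)) { fit <- f2; fallback <- "ml" }
  }
  if (inherits(fit, "try-error") || !conv_ok(fit)) {
    f3 <- suppressWarnings(suppressMessages(try(
      lme4::lmer(value ~ mci + ad + month + mci:month + ad:month +
                   (1 | subject_id),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
      silent = TRUE)))
    if (!inherits(f3, "try-error")) { fit <- f3; fallback <- "intercept_only" }
    else if (inherits(fit, "try-error"))
      stop("mixed-model fit failed for ROI ", roi)
  }

  fe <- lme4::fixef(fit)
  beta <- c(b0 = unname(fe["(Intercept)"]), b1 = unname(fe["mci"]),
            b2 = unname(fe["ad"]), b3 = unname(fe["month"]),
            b4 = unname(fe["mci:month"]), b5 = unname(fe["ad:month"]))
  vc <- lme4::VarCorr(fit)$subject_id
  re <- lme4::ranef(fit)$subject_id
  gamma1 <- stats::setNames(re[["(Intercept)"]], rownames(re))
  gamma2 <- if ("month" %in% colnames(re))
    stats::setNames(re[["month"]], rownames(re))
  else stats::setNames(rep(0, nrow(re)), rownames(re))

  structure(list(
    roi = roi, beta = beta,
    varcor = c(var_g1 = unname(vc[1, 1]),
               var_g2 = if (nrow(vc) > 1) unname(vc[2, 2]) else 0,
               cov_g1g2 = if (nrow(vc) > 1) unname(vc[1, 2]) else 0,
               sigma2 = stats::sigma(fit)^2),
    gamma1 = gamma1, gamma2 = gamma2,
    singular = lme4::isSingular(fit),
    converged = conv_ok(fit),
    fallback = fallback,
    fit_se = sqrt(diag(as.matrix(stats::vcov(fit)))),
    n_subjects = length(gamma2)),
    class = "roi_lmm")
}

#' @export
print.roi_lmm <- function(x, ...) {
  cat(sprintf("Mixed-model fit, ROI %s (%d subjects)\n", x$roi, x$n_subjects))
  print(round(x$beta, 6))
  cat(sprintf("  var(g1) = %.3g, var(g2) = %.3g, sigma2 = %.3g%s%s\n",
              x$varcor["var_g1"], x$varcor["var_g2"], x$varcor["sigma2"],
              if (x$singular) " [singular]" else "",
              if (x$fallback != "none") paste0(" [fallback: ", x$fallback, "]") else ""))
  invisible(x)
}

#' Fit the mixed model for every ROI
#'
#' @param data Long-format phenotype table (see [fit_roi_lmm()]).
#' @param groups Named subject -> group vector, or a covariate data frame
#'   with `subject_id` and `group` columns.
#' @param rois ROIs to fit; default all present in `data`.
#' @return Named list of `"roi_lmm"` fits, class `"roi_lmm_list"`.
#' @export
fit_roi_lmms <- function(data, groups, rois = NULL) {
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$group, groups$subject_id)
  if (is.null(rois)) rois <- unique(data$roi)
  fits <- lapply(rois, function(r) fit_roi_lmm(data, r, groups))
  names(fits) <- rois
  structure(fits, class = "roi_lmm_list")
}

#' @export
print.roi_lmm_list <- function(x, ...) {
  cat(sprintf("Mixed-model fits for %d ROIs (%d singular, %d with fallback)\n",
              length(x),
              sum(vapply(x, function(f) f$singular, logical(1))),
              sum(vapply(x, function(f) f$fallback != "none", logical(1)))))
  invisible(x)
}

#' Predicted per-subject rates of change
#'
#' The predicted rate for subject i at ROI j is the disease-group fixed
#' slope plus the subject's predicted slope deviation:
#' `b3j + b4j MCI_i + b5j AD_i + g2_ij`.
#'
#' @param fits A `"roi_lmm_list"` (or list of `"roi_lmm"`).
#' @param groups Named subject -> group vector, or covariate data frame.
#' @return Subjects x ROIs numeric matrix of rates (units per month).
#' @export
predict_rates <- function(fits, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$group, groups$subject_id)
  subjects <- names(fits[[1]]$gamma2)
  # keep the caller's subject order where the labels provide one
  if (!is.null(names(groups)) && all(subjects %in% names(groups)))
    subjects <- intersect(names(groups), subjects)
  out <- matrix(NA_real_, length(subjects), length(fits),
                dimnames = list(subjects, vapply(fits, function(f) f$roi, "")))
  for (j in seq_along(fits)) {
    f <- fits[[j]]
    g2 <- f$gamma2[subjects]
    if (anyNA(g2)) stop("subject missing from fit for ROI ", f$roi)
    grp <- groups[subjects]
    out[, j] <- f$beta["b3"] + f$beta["b4"] * (grp == "MCI") +
      f$beta["b5"] * (grp == "AD") + g2
  }
  out
}

#' Normality check of the predicted random slopes
#'
#' Advisory Q-Q diagnostics: per ROI, a Shapiro-Wilk test of the conditional
#' modes of the slope random effect, plus the ordered quantile pairs for
#' plotting. With fewer than 10 subjects the check reports insufficient
#' data.
#'
#' @param fits A `"roi_lmm_list"`.
#' @param alpha Flagging threshold (default 0.01).
#' @return Data frame `(roi, n, W, p_value, flagged, note)`.
#' @export
qq_normality_check <- function(fits, alpha = 0.01) {
  rows <- lapply(fits, function(f) {
    g2 <- f$gamma2
    if (length(g2) < 10)
      return(data.frame(roi = f$roi, n = length(g2), W = NA, p_value = NA,
                        flagged = NA, note = "insufficient data"))
    sw <- stats::shapiro.test(g2)
    data.frame(roi = f$roi, n = length(g2), W = unname(sw$statistic),
               p_value = sw$p.value, flagged = sw$p.value < alpha, note = "")
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
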