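#' Derive a disease prevalence from census-style inputs
#'
#' Computes the proportion of a target population affected by a disease as
#' the affected count divided by the size of the age-eligible population,
#' rounded to the nearest half percent (nearest multiple of 0.005, ties
#' rounded half away from zero).
#'
#' @param n_affected Number of affected persons in the population.
#' @param frac_eligible Fraction of the total population in the age-eligible
#'   stratum, in (0, 1).
#' @param total_pop Total population size.
#' @return A single probability, a multiple of 0.005.
#' @examples
#' derive_prevalence_ad(5.2e6, 0.23, 308e6)  # 0.075
#' @export
derive_prevalence_ad <- function(n_affected, frac_eligible, total_pop) {
  stopifnot(is.numeric(n_affected), is.numeric(frac_eligible), is.numeric(total_pop))
  if (n_affected <= 0 || total_pop <= 0)
    stop("'n_affected' and 'total_pop' must be positive")
  if (frac_eligible <= 0 || frac_eligible >= 1)
    stop("'frac_eligible' must be in (0, 1)")
  denom <- frac_eligible * total_pop
  if (denom == 0) stop("zero denominator")
  raw <- n_affected / denom
  round_half_away(raw / 0.005) * 0.005
}

# round to nearest integer, ties away from zero (base round() goes to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Specify assumed population prevalences for the three diagnostic groups
#'
#' @param p_cn,p_mci,p_ad Assumed population prevalences of the cognitively
#'   normal, mild-cognitive-impairment and Alzheimer's-disease groups. Must
#'   each lie in (0, 1) and sum to 1.
#' @return An object of class `"prevalence_spec"`: a named numeric vector.
#' @examples
#' prevalence_spec(0.875, 0.05, 0.075)
#' @export
prevalence_spec <- function(p_cn = 0.875, p_mci = 0.05, p_ad = 0.075) {
  p <- c(CN = p_cn, MCI = p_mci, AD = p_ad)
  if (any(p <= 0) || any(p >= 1)) stop("prevalences must be in (0, 1)")
  if (abs(sum(p) - 1) > 1e-8) stop("prevalences must sum to 1")
  structure(p, class = "prevalence_spec")
}

#' Inverse probability weights for a biased three-group sampling design
#'
#' Case-control style cohorts oversample diseased groups relative to their
#' population frequency. The weight for group D is proportional to
#' `p_D / n_D` (assumed population prevalence over sampled count), and the
#' per-subject weights are standardized so that they sum to the total sample
#' size `n = sum(counts)`. Subjects in the same group share a weight.
#'
#' @param prev A [prevalence_spec()] (or named vector with CN/MCI/AD entries).
#' @param counts Named vector (or list) of sampled subject counts per group;
#'   names must cover CN, MCI, AD.
#' @return An object of class `"weight_vector"`: a list with `group_weights`
#'   (named, full precision), `counts`, `n`, and `rounded` (2-decimal display
#'   values as printed in study reports).
#' @examples
#' w <- compute_weights(prevalence_spec(), c(CN = 179, MCI = 296, AD = 157))
#' w$rounded  # CN 3.09, MCI 0.11, AD 0.30
#' @export
compute_weights <- function(prev, counts) {
  counts <- c(unlist(counts))[c("CN", "MCI", "AD")]
  counts <- stats::setNames(as.numeric(counts), c("CN", "MCI", "AD"))
  if (anyNA(counts)) stop("'counts' must name CN, MCI and AD")
  prev <- c(unclass(prev))[c("CN", "MCI", "AD")]
  if (anyNA(prev)) stop("'prev' must name CN, MCI and AD")
  if (any(counts <= 0)) stop("a group with zero sampled count cannot receive a weight")
  n <- sum(counts)
  raw <- prev / counts
  # standardize so that per-subject weights sum to n
  w <- raw * n / sum(raw * counts)
  structure(list(group_weights = w,
                 counts = counts,
                 n = n,
                 rounded = round(w, 2)),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("Inverse probability weights (standardized to sum to n =", x$n, ")\n")
  print(data.frame(group = names(x$group_weights),
                   n = as.integer(x$counts),
                   weight = round(x$group_weights, 4),
                   printed = sprintf("%.2f", x$rounded),
                   row.names = NULL))
  invisible(x)
}

#' Expand group weights to a per-subject weight vector
#'
#' @param w A `"weight_vector"` from [compute_weights()].
#' @param groups Character vector of group labels (CN/MCI/AD), one per subject.
#' @return Numeric vector of per-subject weights summing to `length(groups)`
#'   when the group composition matches the counts used to build `w`.
#' @export
subject_weights <- function(w, groups) {
  stopifnot(inherits(w, "weight_vector"))
  bad <- setdiff(unique(groups), names(w$group_weights))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  unname(w$group_weights[as.character(groups)])
}
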