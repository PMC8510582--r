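#' Liability threshold for a given prevalence
#'
#' Under the liability threshold model an individual is affected when the
#' standard-normal liability exceeds \eqn{z_K}, the upper-\eqn{K} quantile
#' of the standard normal distribution, so that the tail mass above
#' \eqn{z_K} equals the prevalence \eqn{K}.
#'
#' @param K Disease prevalence, in (0, 1).
#' @return The threshold \eqn{z_K = \Phi^{-1}(1 - K)}.
#' @examples
#' liability_threshold(0.5)   # 0
#' liability_threshold(0.01)  # ~2.326
#' @export
liability_threshold <- function(K) {
  .check_fraction(K, "K", lo_open = TRUE, hi_open = TRUE)
  stats::qnorm(1 - K)
}

#' Risk-reduction metrics from baseline and achieved risk
#'
#' Computes the relative risk reduction \eqn{RRR = 1 - P/P_0} and the
#' absolute risk reduction \eqn{ARR = P_0 - P}, where \eqn{P_0} is the
#' disease probability of a randomly selected embryo (under the same
#' conditioning) and \eqn{P} that of the strategy-selected embryo.
#'
#' @param p_baseline Baseline disease probability \eqn{P_0}, in (0, 1].
#' @param p_disease Disease probability of the selected embryo, in \[0, 1\].
#' @param mc_se Optional Monte-Carlo standard error of `p_disease`.
#' @param se_baseline Optional standard error of `p_baseline`.
#' @return An object of class `"pes_risk"` with elements `p_disease`,
#'   `p_baseline`, `rrr`, `arr`, and (for stochastic estimates) `mc_se`.
#' @examples
#' risk_metrics(0.05, 0.03)  # RRR 40%, ARR 2 points
#' @export
risk_metrics <- function(p_baseline, p_disease, mc_se = NA_real_,
                         se_baseline = NA_real_) {
  .check_fraction(p_baseline, "p_baseline")
  .check_fraction(p_disease, "p_disease")
  if (p_baseline == 0)
    stop("relative risk reduction is undefined for p_baseline = 0",
         call. = FALSE)
  structure(list(p_disease = p_disease, p_baseline = p_baseline,
                 rrr = 1 - p_disease / p_baseline,
                 arr = p_baseline - p_disease,
                 mc_se = mc_se, se_baseline = se_baseline),
            class = "pes_risk")
}

#' @export
print.pes_risk <- function(x, ...) {
  se <- function(v) if (is.finite(v)) sprintf(" (SE %.2g)", v) else ""
  cat("Embryo screening risk result\n")
  cat(sprintf("  P(disease), selected : %.4g%%%s\n",
              100 * x$p_disease, se(100 * x$mc_se)))
  cat(sprintf("  P(disease), baseline : %.4g%%%s\n",
              100 * x$p_baseline, se(100 * x$se_baseline)))
  cat(sprintf("  relative risk reduction : %.1f%%\n", 100 * x$rrr))
  cat(sprintf("  absolute risk reduction : %.2f percentage points\n",
              100 * x$arr))
  invisible(x)
}

#' @export
as.data.frame.pes_risk <- function(x, ...) {
  data.frame(p_disease = x$p_disease, p_baseline = x$p_baseline,
             rrr = x$rrr, arr = x$arr, mc_se = x$mc_se)
}

#' Mean parental PRS from population percentiles
#'
#' Each parent's PRS is read off as a lower-tail quantile of the population
#' PRS distribution \eqn{N(0, r^2_{ps})} (so "98th percentile" means the
#' top 2\%); the shared component \eqn{c} is the mean of the two values.
#'
#' @param percentile_parent1,percentile_parent2 Parental PRS percentiles,
#'   in (0, 1).
#' @param r2 PRS variance on the liability scale, \eqn{r^2_{ps}}.
#' @return The mean parental PRS `c` on the liability scale.
#' @examples
#' percentile_to_c(0.5, 0.5, 0.1)   # 0
#' percentile_to_c(0.98, 0.25, 0.1)
#' @export
percentile_to_c <- function(percentile_parent1, percentile_parent2, r2) {
  .check_fraction(percentile_parent1, "percentile_parent1", lo_open = TRUE, hi_open = TRUE)
  .check_fraction(percentile_parent2, "percentile_parent2", lo_open = TRUE, hi_open = TRUE)
  .check_fraction(r2, "r2", hi_open = TRUE)
  if (r2 == 0) {
    warning("r2 = 0: PRS distribution is degenerate, c = 0")
    return(0)
  }
  s <- sqrt(r2)
  (stats::qnorm(percentile_parent1, sd = s) +
     stats::qnorm(percentile_parent2, sd = s)) / 2
}
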