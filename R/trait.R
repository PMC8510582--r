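# Risk reduction for diseases defined by thresholding a quantitative trait.
# A threshold character with a normally distributed trait is mathematically
# the liability threshold model, so these operations delegate to the
# disease engine after converting the threshold to an implied prevalence.

#' Specify a dichotomized quantitative trait
#'
#' Defines "affected" as lying beyond a threshold in one tail of a normal
#' trait distribution (e.g. IQ below 70, or LDL cholesterol above a
#' clinical cutoff), together with the liability-scale variance the trait
#' PRS explains.
#'
#' @param trait_mean,trait_sd Trait distribution parameters (trait units;
#'   `trait_sd > 0`).
#' @param threshold Affection threshold in trait units.
#' @param tail Which tail is affected: `"lower"` or `"upper"`.
#' @param r2 Variance of the trait explained by the PRS (fraction).
#' @return An object of class `"pes_trait"`.
#' @examples
#' trait_threshold(100, 15, 70, tail = "lower", r2 = 0.05)
#' @export
trait_threshold <- function(trait_mean, trait_sd, threshold,
                            tail = c("lower", "upper"), r2 = 0) {
  stopifnot(is.numeric(trait_mean), is.numeric(threshold))
  if (!is.numeric(trait_sd) || trait_sd <= 0)
    stop("'trait_sd' must be positive", call. = FALSE)
  .check_fraction(r2, "r2", hi_open = TRUE)
  tail <- match.arg(tail)
  spec <- structure(list(trait_mean = trait_mean, trait_sd = trait_sd,
                         threshold = threshold, tail = tail, r2 = r2),
                    class = "pes_trait")
  Kst <- implied_prevalence(spec)
  if (Kst <= 0 || Kst >= 1)
    stop("threshold implies a degenerate prevalence", call. = FALSE)
  spec
}

#' @export
print.pes_trait <- function(x, ...) {
  cat(sprintf("Dichotomized trait: %s tail beyond %g (trait ~ N(%g, %g^2))\n",
              x$tail, x$threshold, x$trait_mean, x$trait_sd))
  cat(sprintf("  implied prevalence: %.4g; PRS r2 = %g\n",
              implied_prevalence(x), x$r2))
  invisible(x)
}

#' Prevalence implied by a trait threshold
#'
#' Tail mass of the normal trait distribution beyond the affection
#' threshold.
#'
#' @param spec A [trait_threshold()].
#' @return Implied prevalence, in (0, 1).
#' @examples
#' implied_prevalence(trait_threshold(100, 15, 70, "lower"))  # pnorm(-2)
#' @export
implied_prevalence <- function(spec) {
  stopifnot(inherits(spec, "pes_trait"))
  z <- (spec$threshold - spec$trait_mean) / spec$trait_sd
  if (spec$tail == "lower") stats::pnorm(z) else stats::pnorm(z, lower.tail = FALSE)
}

#' Fraction of the affected tail within a given gain of the threshold
#'
#' Among affected individuals (those beyond the threshold), the fraction
#' whose trait value lies within `gain` of the threshold -- i.e. those who
#' would cross back over the threshold under a uniform favorable shift of
#' `gain` trait units.
#'
#' @param spec A [trait_threshold()].
#' @param gain Favorable shift in trait units (`gain >= 0`).
#' @return Fraction in \[0, 1\], strictly increasing in `gain`.
#' @examples
#' # among individuals with IQ < 70, those in [67.5, 70]: ~33.5%
#' tail_retention_fraction(trait_threshold(100, 15, 70, "lower"), 2.5)
#' @export
tail_retention_fraction <- function(spec, gain) {
  stopifnot(inherits(spec, "pes_trait"), is.numeric(gain), gain >= 0)
  m <- spec$trait_mean; s <- spec$trait_sd; thr <- spec$threshold
  if (spec$tail == "lower") {
    tailmass <- stats::pnorm(thr, m, s)
    (tailmass - stats::pnorm(thr - gain, m, s)) / tailmass
  } else {
    tailmass <- stats::pnorm(thr, m, s, lower.tail = FALSE)
    (tailmass - stats::pnorm(thr + gain, m, s, lower.tail = FALSE)) / tailmass
  }
}

#' Risk reduction for a dichotomized trait under lowest-risk prioritization
#'
#' Selecting the embryo with the most favorable trait PRS (lowest for a
#' lower-tail disease, highest for an upper-tail one) is, by the symmetry
#' of the normal model, the lowest-risk prioritization strategy for a
#' disease with prevalence equal to the implied tail mass and PRS variance
#' `spec$r2`; the computation delegates to [risk_lrp()].
#'
#' @param spec A [trait_threshold()] with `r2` set.
#' @param n Number of viable embryos.
#' @return A `"pes_risk"` object (baseline = implied prevalence).
#' @examples
#' iq <- trait_threshold(100, 15, 70, "lower", r2 = 0.05)
#' rrr_dichotomized(iq, n = 5)
#' @export
rrr_dichotomized <- function(spec, n) {
  stopifnot(inherits(spec, "pes_trait"))
  Kst <- implied_prevalence(spec)
  scn <- pes_scenario(K = Kst, r2 = spec$r2, n = n)
  risk_metrics(Kst, risk_lrp(scn))
}
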