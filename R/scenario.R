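#' Define a polygenic embryo screening scenario
#'
#' A scenario bundles the parameters of the liability threshold model (LTM)
#' that drive every risk calculation in the package: the disease prevalence
#' \eqn{K}, the fraction of liability variance explained by the polygenic
#' risk score (PRS) \eqn{r^2_{ps}}, the number of viable embryos \eqn{n},
#' and the selection strategy.
#'
#' Liabilities are standardized so the total liability variance is 1; the
#' PRS lives on the same scale with variance \eqn{r^2_{ps}}.  Within a
#' couple the embryo score decomposes as \eqn{s_i = x_i + c} with a shared
#' component \eqn{c \sim N(0, r^2_{ps}/2)} (the mean parental PRS) and
#' embryo-specific components \eqn{x_i \sim N(0, r^2_{ps}/2)}.
#'
#' Strategies:
#' \describe{
#'   \item{`"lrp"`}{lowest-risk prioritization: implant the embryo with the
#'     minimum PRS.}
#'   \item{`"hre"`}{high-risk exclusion: among embryos whose PRS is below
#'     the top-`q` population cutoff, implant one at random; if all `n`
#'     embryos are high-risk, implant a random embryo.}
#'   \item{`"hre-fallback-lowest"`}{as `"hre"`, but if all embryos are
#'     high-risk the one with the lowest PRS is implanted; at `q = 1` this
#'     reduces to `"lrp"`.}
#' }
#'
#' @param K Disease prevalence, in (0, 1).
#' @param r2 Proportion of liability variance explained by the PRS
#'   (\eqn{r^2_{ps}}), in \[0, 1).
#' @param n Number of viable embryos (integer, >= 1).
#' @param strategy Selection strategy; one of `"lrp"`, `"hre"`,
#'   `"hre-fallback-lowest"`.
#' @param q High-risk fraction: embryos in the top `q` of the population
#'   PRS distribution are excluded.  Required for the HRE strategies and
#'   ignored (with a warning if supplied) for `"lrp"`.
#'
#' @return An object of class `"pes_scenario"`.
#' @examples
#' pes_scenario(K = 0.01, r2 = 0.08, n = 5)
#' pes_scenario(K = 0.05, r2 = 0.3, n = 5, strategy = "hre", q = 0.02)
#' @export
pes_scenario <- function(K, r2, n, strategy = c("lrp", "hre", "hre-fallback-lowest"),
                         q = NULL) {
  .check_fraction(K, "K", lo_open = TRUE, hi_open = TRUE)
  .check_fraction(r2, "r2", hi_open = TRUE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  strategy <- match.arg(strategy)
  if (strategy == "lrp") {
    if (!is.null(q)) warning("'q' is ignored under the LRP strategy")
    q <- NULL
  } else {
    if (is.null(q)) stop("'q' is required for the HRE strategies", call. = FALSE)
    .check_fraction(q, "q")
  }
  structure(list(K = K, r2 = r2, n = as.integer(n),
                 strategy = strategy, q = q),
            class = "pes_scenario")
}

#' @export
print.pes_scenario <- function(x, ...) {
  cat("Polygenic embryo screening scenario\n")
  cat(sprintf("  prevalence K        : %g\n", x$K))
  cat(sprintf("  PRS variance r2_ps  : %g\n", x$r2))
  cat(sprintf("  embryos n           : %d\n", x$n))
  cat(sprintf("  strategy            : %s%s\n", x$strategy,
              if (!is.null(x$q)) sprintf(" (q = %g)", x$q) else ""))
  invisible(x)
}

#' Describe a couple for conditional risk analyses
#'
#' Collects what is known about the prospective parents: either their PRSs
#' (as liability-scale values or population percentiles, summarized by the
#' mean parental PRS \eqn{c}), or their disease statuses together with the
#' narrow-sense heritability \eqn{h^2} needed to interpret them.
#'
#' @param c Mean parental PRS on the liability scale.  Mutually exclusive
#'   with `percentiles`.
#' @param percentiles Length-2 vector of the parents' PRS percentiles
#'   (lower-tail, in (0,1)); converted with [percentile_to_c()] using the
#'   scenario's `r2` at computation time.
#' @param h2 Narrow-sense heritability of liability, in \[0, 1\]; required
#'   for disease-status conditioning and must satisfy `h2 >= r2`.
#' @param status1,status2 Parental disease status: `"affected"`,
#'   `"unaffected"`, or `"unknown"` (unknown is marginalized over).
#'
#' @return An object of class `"pes_couple"`.
#' @examples
#' pes_couple(percentiles = c(0.98, 0.25))
#' pes_couple(h2 = 0.4, status1 = "affected", status2 = "unaffected")
#' @export
pes_couple <- function(c = NULL, percentiles = NULL, h2 = NULL,
                       status1 = "unknown", status2 = "unknown") {
  if (!is.null(c) && !is.null(percentiles))
    stop("give either 'c' or 'percentiles', not both", call. = FALSE)
  if (!is.null(percentiles)) {
    stopifnot(length(percentiles) == 2L)
    for (p in percentiles) .check_fraction(p, "percentiles", lo_open = TRUE, hi_open = TRUE)
  }
  if (!is.null(h2)) .check_fraction(h2, "h2")
  sts <- c("affected", "unaffected", "unknown")
  status1 <- match.arg(status1, sts)
  status2 <- match.arg(status2, sts)
  if ((status1 != "unknown" || status2 != "unknown") && is.null(h2))
    stop("'h2' is required when conditioning on parental disease status",
         call. = FALSE)
  structure(list(c = c, percentiles = percentiles, h2 = h2,
                 status1 = status1, status2 = status2),
            class = "pes_couple")
}

#' @export
print.pes_couple <- function(x, ...) {
  cat("Couple context\n")
  if (!is.null(x$c)) cat(sprintf("  mean parental PRS c : %g\n", x$c))
  if (!is.null(x$percentiles))
    cat(sprintf("  parental percentiles: %g, %g\n",
                x$percentiles[1], x$percentiles[2]))
  if (!is.null(x$h2)) cat(sprintf("  heritability h2     : %g\n", x$h2))
  cat(sprintf("  statuses            : %s, %s\n", x$status1, x$status2))
  invisible(x)
}

# resolve the shared component c for a couple under a given scenario
.couple_c <- function(couple, r2) {
  if (!is.null(couple$c)) return(couple$c)
  if (!is.null(couple$percentiles))
    return(percentile_to_c(couple$percentiles[1], couple$percentiles[2], r2))
  NULL
}
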