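# Deterministic risk computations under the liability threshold model.
#
# Generative model, conditional on a couple's shared score component c:
#   embryo score      s_i = c + x_i,   x_i ~ N(0, r2/2) iid
#   embryo liability  y_i = s_i + e_i, e_i ~ N(0, 1 - r2) iid
#   affected          y_i > z_K
# and unconditionally c ~ N(0, r2/2).  Selection acts on the scores only.

# Disease probability of the selected embryo when its score is mu + x with
# x drawn from the selection-induced distribution of the embryo-specific
# component, and the residual liability has sd s_res.  `trunc_at` is the
# threshold on x (score cutoff minus shared score component) used by the
# HRE strategies.
.risk_sel_core <- function(mu, zK, sx, s_res, n, strategy, trunc_at = NULL) {
  g <- function(x) stats::pnorm((zK - mu - x) / s_res, lower.tail = FALSE)
  if (sx == 0) return(g(0))
  lo <- -.INT_SD_SPAN * sx
  hi <- .INT_SD_SPAN * sx

  if (strategy == "lrp") {
    # density of the minimum of n iid N(0, sx^2)
    f <- function(x) n / sx * stats::dnorm(x / sx) *
      stats::pnorm(x / sx, lower.tail = FALSE)^(n - 1) * g(x)
    return(.integrate(f, lo, hi))
  }

  t0 <- trunc_at
  Phi_u <- stats::pnorm(t0 / sx)            # P(one embryo is not high-risk)
  # E[#fraction] of the "at least one below cutoff" branch, divided by Phi_u:
  # (1 - (1 - Phi_u)^n) / Phi_u, with the n limit as Phi_u -> 0
  wA <- if (Phi_u < 1e-14) n else -expm1(n * log1p(-Phi_u)) / Phi_u
  IA <- if (t0 > lo)
    .integrate(function(x) stats::dnorm(x / sx) / sx * g(x), lo, min(t0, hi))
  else 0

  if (strategy == "hre") {
    # all high-risk: a random embryo, i.e. x truncated below at t0
    p_hi <- 1 - Phi_u
    IB <- if (t0 < hi && p_hi > 0)
      p_hi^(n - 1) *
        .integrate(function(x) stats::dnorm(x / sx) / sx * g(x), max(t0, lo), hi)
    else 0
  } else {                                  # hre-fallback-lowest
    # all high-risk: the minimum of n iid truncated-below normals;
    # joint density n*phi(x)*(1-Phi(x))^(n-1) on x > t0 already carries the
    # probability of the branch, so no division is needed
    IB <- if (t0 < hi)
      .integrate(function(x) n * stats::dnorm(x / sx) / sx *
                   stats::pnorm(x / sx, lower.tail = FALSE)^(n - 1) * g(x),
                 max(t0, lo), hi)
    else 0
  }
  wA * IA + IB
}

# selected-embryo risk conditional on the shared score component c
.risk_sel_given_c <- function(c0, scn) {
  zK <- liability_threshold(scn$K)
  sx <- sqrt(scn$r2 / 2)
  s_res <- sqrt(1 - scn$r2)
  trunc_at <- if (scn$strategy == "lrp") NULL
  else stats::qnorm(1 - scn$q) * sqrt(scn$r2) - c0
  .risk_sel_core(c0, zK, sx, s_res, scn$n, scn$strategy, trunc_at)
}

# alternative form for LRP (condition on the residual instead of the
# minimum score); used to cross-validate the order-statistic route
.risk_lrp_given_c_alt <- function(c0, scn) {
  zK <- liability_threshold(scn$K)
  sx <- sqrt(scn$r2 / 2)
  s_res <- sqrt(1 - scn$r2)
  if (scn$r2 == 0) return(stats::pnorm(zK - c0, lower.tail = FALSE))
  f <- function(e) stats::dnorm(e / s_res) / s_res *
    stats::pnorm((zK - c0 - e) / sx, lower.tail = FALSE)^scn$n
  .integrate(f, -.INT_SD_SPAN, .INT_SD_SPAN)
}

# vectorized LRP given-c risk on a fixed Gauss-Legendre grid (for dense
# per-couple curves); agrees with the adaptive route to ~1e-10
.risk_lrp_given_c_vec <- function(cvec, scn, n_nodes = 257) {
  zK <- liability_threshold(scn$K)
  sx <- sqrt(scn$r2 / 2)
  s_res <- sqrt(1 - scn$r2)
  if (scn$r2 == 0)
    return(stats::pnorm(zK - cvec, lower.tail = FALSE))
  gl <- pracma::gaussLegendre(n_nodes, -.INT_SD_SPAN * sx, .INT_SD_SPAN * sx)
  fmin <- scn$n / sx * stats::dnorm(gl$x / sx) *
    stats::pnorm(gl$x / sx, lower.tail = FALSE)^(scn$n - 1)
  G <- stats::pnorm((zK - outer(cvec, gl$x, `+`)) / s_res, lower.tail = FALSE)
  as.vector(G %*% (gl$w * fmin))
}

#' Disease risk of a randomly selected embryo given the parental PRS
#'
#' Conditional on the mean parental PRS \eqn{c}, a random embryo's
#' liability is \eqn{c + x + e \sim N(c, 1 - r^2_{ps}/2)}, so its disease
#' probability is \eqn{1 - \Phi((z_K - c)/\sqrt{1 - r^2_{ps}/2})}.
#' This is the baseline against which conditional risk reductions are
#' measured.
#'
#' @param scenario A [pes_scenario()].
#' @param c Mean parental PRS on the liability scale (vectorized).
#' @return Disease probability (vector).
#' @export
risk_random_given_c <- function(scenario, c) {
  stopifnot(inherits(scenario, "pes_scenario"))
  zK <- liability_threshold(scenario$K)
  stats::pnorm((zK - c) / sqrt(1 - scenario$r2 / 2), lower.tail = FALSE)
}

# population-averaged disease probability of the selected embryo
.risk_uncond <- function(scn) {
  if (scn$r2 == 0 || scn$n == 1L) return(scn$K)
  if (scn$strategy != "lrp" && (scn$q == 0 || scn$q == 1)) {
    # q = 0: nothing flagged; q = 1 plain HRE: everything flagged -> random
    if (scn$strategy == "hre" || scn$q == 0) return(scn$K)
    # fallback variant at q = 1 reduces to LRP
    scn <- pes_scenario(scn$K, scn$r2, scn$n, "lrp")
    return(.risk_uncond(scn))
  }
  sc <- sqrt(scn$r2 / 2)
  .integrate(function(cv)
    vapply(cv, function(c0) .risk_sel_given_c(c0, scn), 0) *
      stats::dnorm(cv / sc) / sc,
    -.INT_SD_SPAN * sc, .INT_SD_SPAN * sc)
}

#' Population-averaged disease risk under lowest-risk prioritization
#'
#' Probability that the implanted embryo becomes affected when, in every
#' batch of `n` embryos, the one with the minimum PRS is selected.
#' Conditional on the shared component the selected score is the minimum of
#' `n` iid \eqn{N(0, r^2_{ps}/2)} draws; the residual liability tail and
#' the shared component are then integrated out by adaptive quadrature.
#'
#' @param scenario A [pes_scenario()]; `K`, `r2` and `n` are used.
#' @return Disease probability \eqn{P(\mathrm{disease})}, in (0, K\].
#' @examples
#' scn <- pes_scenario(K = 0.01, r2 = 0.08, n = 5)
#' p <- risk_lrp(scn)
#' 1 - p / scn$K   # relative risk reduction, ~0.52
#' @export
risk_lrp <- function(scenario) {
  stopifnot(inherits(scenario, "pes_scenario"))
  scn <- pes_scenario(scenario$K, scenario$r2, scenario$n, "lrp")
  .risk_uncond(scn)
}

#' Population-averaged disease risk under high-risk exclusion
#'
#' Embryos whose PRS falls in the top `q` of the population score
#' distribution (score above \eqn{z_q \cdot r_{ps}}) are excluded and a
#' random remaining embryo is implanted; if all `n` embryos are high-risk a
#' random embryo is implanted.  `risk_hre_fallback_lowest()` differs only
#' in the all-high-risk branch, where the lowest-scoring embryo is taken,
#' and reduces to [risk_lrp()] at `q = 1`.
#'
#' @param scenario A [pes_scenario()] with `q` set.
#' @return Disease probability; equals `K` at `q = 0` and (for plain HRE)
#'   at `q = 1`.
#' @examples
#' scn <- pes_scenario(K = 0.05, r2 = 0.3, n = 5, strategy = "hre", q = 0.02)
#' 1 - risk_hre(scn) / scn$K   # ~0.09
#' @export
risk_hre <- function(scenario) {
  stopifnot(inherits(scenario, "pes_scenario"))
  if (is.null(scenario$q)) stop("'q' must be set for HRE", call. = FALSE)
  scn <- pes_scenario(scenario$K, scenario$r2, scenario$n, "hre", q = scenario$q)
  .risk_uncond(scn)
}

#' @rdname risk_hre
#' @export
risk_hre_fallback_lowest <- function(scenario) {
  stopifnot(inherits(scenario, "pes_scenario"))
  if (is.null(scenario$q)) stop("'q' must be set for HRE", call. = FALSE)
  scn <- pes_scenario(scenario$K, scenario$r2, scenario$n,
                      "hre-fallback-lowest", q = scenario$q)
  .risk_uncond(scn)
}

#' Population-averaged risk result for a scenario
#'
#' Dispatches on the scenario's strategy and packages the selected-embryo
#' risk together with the population prevalence baseline as a
#' [risk_metrics()] result.
#'
#' @param scenario A [pes_scenario()].
#' @return A `"pes_risk"` object (baseline = prevalence `K`).
#' @examples
#' analytic_risk(pes_scenario(K = 0.2, r2 = 0.17, n = 5))
#' @export
analytic_risk <- function(scenario) {
  stopifnot(inherits(scenario, "pes_scenario"))
  risk_metrics(scenario$K, .risk_uncond(scenario))
}

#' Conditional risk result given the mean parental PRS
#'
#' Computes the disease probability of the strategy-selected embryo and of
#' a randomly selected embryo, both conditional on the couple's mean
#' parental PRS \eqn{c}, and the implied per-couple risk reductions.
#'
#' @param scenario A [pes_scenario()].
#' @param c Mean parental PRS on the liability scale (see
#'   [percentile_to_c()] to convert population percentiles).
#' @return A `"pes_risk"` object with `p_baseline = risk_random_given_c()`.
#' @examples
#' scn <- pes_scenario(K = 0.05, r2 = 0.1, n = 5)
#' risk_given_c(scn, percentile_to_c(0.98, 0.25, scn$r2))
#' @export
risk_given_c <- function(scenario, c) {
  stopifnot(inherits(scenario, "pes_scenario"), is.numeric(c), length(c) == 1L)
  p0 <- risk_random_given_c(scenario, c)
  p <- if (scenario$r2 == 0 || scenario$n == 1L) p0
  else .risk_sel_given_c(c, scenario)
  risk_metrics(p0, p)
}

#' Distribution of the per-couple relative risk reduction
#'
#' Evaluates the per-couple RRR, \eqn{pcRRR(c) = 1 -
#' P_s(\mathrm{disease}|c)/P_r(\mathrm{disease}|c)}, on an equal-mass grid
#' of mid-quantiles of the shared-component distribution
#' \eqn{c \sim N(0, r^2_{ps}/2)} (quantile \eqn{(i-1/2)/m}), covering all
#' hypothetical couples in the population.
#'
#' @param scenario A [pes_scenario()].
#' @param n_quantiles Number of equal-mass grid points (>= 2);
#'   10^4 reproduces the published resolution.
#' @return An object of class `"pes_pccurve"`: a data frame with columns
#'   `quantile`, `c`, `p_selected`, `p_random`, `pcrrr`, `weight`.
#' @examples
#' pc <- pcrrr_distribution(pes_scenario(K = 0.05, r2 = 0.1, n = 5), 200)
#' summary(pc)
#' @export
pcrrr_distribution <- function(scenario, n_quantiles = 1e4) {
  stopifnot(inherits(scenario, "pes_scenario"),
            is.numeric(n_quantiles), n_quantiles >= 2)
  m <- as.integer(n_quantiles)
  qs <- (seq_len(m) - 0.5) / m
  cg <- stats::qnorm(qs, sd = sqrt(scenario$r2 / 2))
  p0 <- risk_random_given_c(scenario, cg)
  ps <- if (scenario$n == 1L || scenario$r2 == 0) p0
  else if (scenario$strategy == "lrp") .risk_lrp_given_c_vec(cg, scenario)
  else vapply(cg, function(c0) .risk_sel_given_c(c0, scenario), 0)
  out <- data.frame(quantile = qs, c = cg, p_selected = ps, p_random = p0,
                    pcrrr = 1 - ps / p0, weight = rep(1 / m, m))
  class(out) <- c("pes_pccurve", "data.frame")
  attr(out, "scenario") <- scenario
  out
}

#' @export
summary.pes_pccurve <- function(object, ...) {
  x <- object$pcrrr
  w <- object$weight
  c(mean = sum(w * x),
    sd = sqrt(sum(w * (x - sum(w * x))^2)),
    stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975)))
}

#' @export
print.pes_pccurve <- function(x, ...) {
  cat(sprintf("Per-couple RRR curve (%d quantiles of c)\n", nrow(x)))
  print(round(summary(x), 4))
  invisible(x)
}

#' @export
plot.pes_pccurve <- function(x, type = c("density", "curve"), ...) {
  type <- match.arg(type)
  if (type == "density") {
    graphics::hist(x$pcrrr, breaks = 50, freq = FALSE,
                   main = "Per-couple relative risk reduction",
                   xlab = "pcRRR", ...)
  } else {
    graphics::plot(x$quantile, x$pcrrr, type = "l",
                   xlab = "quantile of mean parental PRS c",
                   ylab = "pcRRR", ...)
  }
  invisible(x)
}

# ---- parental disease-status conditioning --------------------------------
#
# Parent j has liability y_j = t_j + e_j with t_j = s_j + g_j collecting the
# score (var r2) and non-score genetic (var h2 - r2) components, so
# t_j ~ N(0, h2) and e_j ~ N(0, 1 - h2).  Offspring receive the mid-parent
# value of both heritable components plus segregation noise (half the
# population variance each), so with T = (t1 + t2)/2:
#   random embryo liability | T        ~ N(T, 1 - h2/2)
#   selected embryo liability | T, x   =  T + x + N(0, 1 - h2/2 - r2/2)
# where x is the selection-induced embryo-specific score component.  For the
# HRE strategies the score cutoff acts on c + x with c = (s1 + s2)/2, and
# c | T ~ N(T r2/h2, r2 (h2 - r2) / (2 h2)) is integrated out.

.status_likelihood <- function(t, status, zK, sde) {
  switch(status,
         affected   = stats::pnorm((zK - t) / sde, lower.tail = FALSE),
         unaffected = stats::pnorm((zK - t) / sde),
         unknown    = rep(1, length(t)))
}

#' Risk result conditional on parental disease status
#'
#' Integrates the disease probability of the selected (and of a random)
#' embryo over the posterior distribution of the parental heritable
#' liability components given each parent's affection status, under the
#' liability threshold model with narrow-sense heritability `h2`
#' (from `couple$h2`, which must satisfy `h2 >= r2`).  `"unknown"` statuses
#' are marginalized over.
#'
#' @param scenario A [pes_scenario()].
#' @param couple A [pes_couple()] with `h2` and parental statuses.
#' @param n_nodes Gauss-Legendre nodes per parental dimension.
#' @return A `"pes_risk"` object; `p_baseline` is the risk of a randomly
#'   chosen embryo under the same conditioning.
#' @examples
#' scn <- pes_scenario(K = 0.05, r2 = 0.1, n = 5)
#' cpl <- pes_couple(h2 = 0.4, status1 = "affected", status2 = "unaffected")
#' risk_given_parental_status(scn, cpl)  # baseline ~10.0%, selected ~5.8%
#' @export
risk_given_parental_status <- function(scenario, couple, n_nodes = 201) {
  stopifnot(inherits(scenario, "pes_scenario"), inherits(couple, "pes_couple"))
  h2 <- couple$h2
  if (is.null(h2)) stop("couple$h2 is required", call. = FALSE)
  r2 <- scenario$r2
  if (h2 < r2)
    stop("h2 must be >= r2 (score variance cannot exceed genetic variance)",
         call. = FALSE)
  K <- scenario$K
  zK <- liability_threshold(K)
  n <- scenario$n

  if (h2 == 0) {
    # status carries no heritable signal
    p0 <- K
    ps <- if (r2 == 0 || n == 1L) K else .risk_uncond(scenario)
    return(risk_metrics(p0, ps))
  }

  st <- sqrt(h2)
  sde <- sqrt(1 - h2)
  gl <- pracma::gaussLegendre(n_nodes, -.INT_SD_SPAN, .INT_SD_SPAN)
  base_w <- gl$w * stats::dnorm(gl$x / st) / st
  postw <- function(status) {
    w <- base_w * .status_likelihood(gl$x, status, zK, sde)
    w / sum(w)
  }
  w1 <- postw(couple$status1)
  w2 <- postw(couple$status2)

  s_rand <- sqrt(1 - h2 / 2)
  s_rem <- sqrt(1 - h2 / 2 - r2 / 2)
  sx <- sqrt(r2 / 2)

  # selected-embryo risk as a function of the mid-parent heritable value T
  risk_sel_T <- function(T0) {
    if (r2 == 0 || n == 1L)
      return(stats::pnorm((zK - T0) / s_rand, lower.tail = FALSE))
    if (scenario$strategy == "lrp")
      return(.risk_sel_core(T0, zK, sx, s_rem, n, "lrp"))
    thr <- stats::qnorm(1 - scenario$q) * sqrt(r2)
    vc <- r2 * (h2 - r2) / (2 * h2)
    mc <- T0 * r2 / h2
    if (vc < 1e-12)
      return(.risk_sel_core(T0, zK, sx, s_rem, n, scenario$strategy, thr - mc))
    glc <- pracma::gaussLegendre(41, mc - .INT_SD_SPAN * sqrt(vc),
                                 mc + .INT_SD_SPAN * sqrt(vc))
    dens <- stats::dnorm(glc$x, mc, sqrt(vc))
    vals <- vapply(glc$x, function(cc)
      .risk_sel_core(T0, zK, sx, s_rem, n, scenario$strategy, thr - cc), 0)
    sum(glc$w * dens * vals)
  }

  # T = (t1 + t2)/2 over the product posterior; evaluate the smooth risk
  # curves on a spline grid and sum product weights
  Tmat <- outer(gl$x, gl$x, function(a, b) (a + b) / 2)
  W <- outer(w1, w2)
  grid <- seq(min(Tmat), max(Tmat), length.out = 401)
  sf_sel <- stats::splinefun(grid, vapply(grid, risk_sel_T, 0))
  p_sel <- sum(W * sf_sel(Tmat))
  p_rand <- sum(W * stats::pnorm((zK - Tmat) / s_rand, lower.tail = FALSE))
  risk_metrics(p_rand, p_sel)
}
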