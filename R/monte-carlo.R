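# Vectorized Monte-Carlo simulation of embryo batches and selection.

# pick the selected embryo index per batch for a score matrix S (batches x n).
# Random picks use a random-key argmax (uniform keys, masked to the eligible
# set), which is fully vectorized and uniform over the eligible embryos.
.select_index <- function(S, strategy, thr = NULL) {
  n <- ncol(S)
  B <- nrow(S)
  if (strategy == "lrp") return(max.col(-S, ties.method = "first"))
  ok <- S < thr
  any_ok <- rowSums(ok) > 0
  U <- matrix(stats::runif(B * n), B, n)
  pick_all <- max.col(U)                 # random among all embryos
  Um <- U
  Um[!ok] <- -1
  pick_ok <- max.col(Um)                 # random among eligible embryos
  pick <- ifelse(any_ok, pick_ok, pick_all)
  if (strategy == "hre-fallback-lowest" && any(!any_ok)) {
    low <- max.col(-S, ties.method = "first")
    pick[!any_ok] <- low[!any_ok]
  }
  pick
}

#' Monte-Carlo simulation of embryo selection
#'
#' Simulates batches of `n` embryos from the liability threshold model
#' (shared component `c ~ N(0, r2/2)`, embryo-specific scores
#' `x_i ~ N(0, r2/2)`, residual liabilities `e_i ~ N(0, 1 - r2)`), selects
#' one embryo per batch according to the scenario's strategy and one at
#' random as the baseline arm, and returns the affected fractions with
#' binomial standard errors.  Identical seeds give bit-identical results;
#' the caller's RNG state is untouched.
#'
#' @param scenario A [pes_scenario()].
#' @param n_batches Number of simulated batches (couples).
#' @param seed Integer seed (mandatory).
#' @param condition_c If non-`NULL`, fix the shared component at this value
#'   instead of drawing it.
#' @param condition_status Optional [pes_couple()] with parental statuses
#'   (and `h2`); couples are rejection-sampled to match the statuses.
#' @param chunk_size Batches simulated per chunk (memory cap).
#' @return A `"pes_risk"` object with Monte-Carlo standard errors.
#' @examples
#' scn <- pes_scenario(K = 0.01, r2 = 0.08, n = 5)
#' simulate_selection(scn, n_batches = 1e5, seed = 1)
#' @export
simulate_selection <- function(scenario, n_batches, seed,
                               condition_c = NULL, condition_status = NULL,
                               chunk_size = 1e5) {
  stopifnot(inherits(scenario, "pes_scenario"), n_batches >= 1)
  if (!is.null(condition_c) && !is.null(condition_status))
    stop("condition on either c or parental status, not both", call. = FALSE)
  K <- scenario$K; r2 <- scenario$r2; n <- scenario$n
  zK <- liability_threshold(K)
  thr <- if (scenario$strategy != "lrp") stats::qnorm(1 - scenario$q) * sqrt(r2)

  if (!is.null(condition_status)) {
    stopifnot(inherits(condition_status, "pes_couple"))
    h2 <- condition_status$h2
    if (is.null(h2)) stop("condition_status$h2 is required", call. = FALSE)
    if (h2 < r2) stop("h2 must be >= r2", call. = FALSE)
    # crude lower bound on the acceptance rate from the marginal prevalence
    acc <- prod(vapply(c(condition_status$status1, condition_status$status2),
                       function(s) switch(s, affected = K,
                                          unaffected = 1 - K, unknown = 1), 0))
    if (acc < 1e-5)
      stop("parental-status acceptance rate below 1e-5; ",
           "use risk_given_parental_status() instead", call. = FALSE)
  }

  .with_seed(seed, {
    n_sel <- 0; n_rand <- 0; done <- 0
    while (done < n_batches) {
      B <- min(chunk_size, n_batches - done)
      if (!is.null(condition_status)) {
        draws <- .draw_status_batches(B, scenario, condition_status, zK)
        cc <- draws$c; mm <- draws$m
        s_res <- sqrt(1 - h2)                 # embryo environment
        X <- matrix(stats::rnorm(B * n, sd = sqrt(r2 / 2)), B, n)
        V <- matrix(stats::rnorm(B * n, sd = sqrt((h2 - r2) / 2)), B, n)
        S <- X + cc
        Y <- S + mm + V + matrix(stats::rnorm(B * n, sd = s_res), B, n)
      } else {
        cc <- if (is.null(condition_c))
          stats::rnorm(B, sd = sqrt(r2 / 2)) else rep(condition_c, B)
        X <- matrix(stats::rnorm(B * n, sd = sqrt(r2 / 2)), B, n)
        S <- X + cc
        Y <- S + matrix(stats::rnorm(B * n, sd = sqrt(1 - r2)), B, n)
      }
      pick <- .select_index(S, scenario$strategy, thr)
      rnd <- sample.int(n, B, replace = TRUE)
      i <- seq_len(B)
      n_sel <- n_sel + sum(Y[cbind(i, pick)] > zK)
      n_rand <- n_rand + sum(Y[cbind(i, rnd)] > zK)
      done <- done + B
    }
    p_sel <- n_sel / n_batches
    p_rand <- n_rand / n_batches
    risk_metrics(p_rand, p_sel,
                 mc_se = sqrt(p_sel * (1 - p_sel) / n_batches),
                 se_baseline = sqrt(p_rand * (1 - p_rand) / n_batches))
  })
}

# rejection-sample couples matching the requested statuses; returns the
# shared score component c and mid-parent non-score genetic component m
.draw_status_batches <- function(B, scn, couple, zK) {
  h2 <- couple$h2; r2 <- scn$r2
  cs <- numeric(0); ms <- numeric(0)
  want <- function(y, status) switch(status,
    affected = y > zK, unaffected = y <= zK, unknown = rep(TRUE, length(y)))
  while (length(cs) < B) {
    M <- max(2 * B, 1e4)
    s1 <- stats::rnorm(M, sd = sqrt(r2));  s2 <- stats::rnorm(M, sd = sqrt(r2))
    g1 <- stats::rnorm(M, sd = sqrt(h2 - r2)); g2 <- stats::rnorm(M, sd = sqrt(h2 - r2))
    y1 <- s1 + g1 + stats::rnorm(M, sd = sqrt(1 - h2))
    y2 <- s2 + g2 + stats::rnorm(M, sd = sqrt(1 - h2))
    keep <- want(y1, couple$status1) & want(y2, couple$status2)
    cs <- c(cs, ((s1 + s2) / 2)[keep])
    ms <- c(ms, ((g1 + g2) / 2)[keep])
  }
  list(c = cs[seq_len(B)], m = ms[seq_len(B)])
}

#' Define a two-disease pleiotropy scenario
#'
#' Parameters for simulating selection on a target disease whose PRS has
#' genetic correlation `rho` with a second, unscreened disease.
#'
#' @param rho Genetic correlation between the two disease scores, in
#'   \[-1, 1\].
#' @param K1,K2 Prevalences of the target and correlated disease.
#' @param r2_1,r2_2 Liability-scale PRS variances of the two diseases.
#' @param n Embryos per couple.
#' @param n_couples Number of simulated couples.
#' @param seed Integer seed.
#' @return An object of class `"pes_pleiotropy_scenario"`.
#' @export
pleiotropy_scenario <- function(rho, K1, K2, r2_1, r2_2, n, n_couples, seed) {
  .check_fraction(rho, "rho", lo = -1, hi = 1)
  .check_fraction(K1, "K1", lo_open = TRUE, hi_open = TRUE)
  .check_fraction(K2, "K2", lo_open = TRUE, hi_open = TRUE)
  .check_fraction(r2_1, "r2_1", hi_open = TRUE)
  .check_fraction(r2_2, "r2_2", hi_open = TRUE)
  stopifnot(n >= 1, n == round(n), n_couples >= 1)
  # covariance of the half-variance components; PSD check of the 2x2 blocks
  cv <- rho * sqrt(r2_1 * r2_2) / 2
  if (r2_1 * r2_2 / 4 - cv^2 < -1e-12)
    stop("score covariance matrix is not positive semi-definite", call. = FALSE)
  structure(list(rho = rho, K1 = K1, K2 = K2, r2_1 = r2_1, r2_2 = r2_2,
                 n = as.integer(n), n_couples = as.integer(n_couples),
                 seed = seed),
            class = "pes_pleiotropy_scenario")
}

#' Simulate pleiotropic risk under lowest-risk prioritization
#'
#' Per couple, draws bivariate shared components and bivariate
#' embryo-specific components with the genetic covariance
#' \eqn{\rho\sqrt{r^2_1 r^2_2}} split equally between the shared and
#' specific parts; residual (environmental) liabilities are independent
#' across diseases.  The embryo with the lowest target-disease PRS is
#' selected and compared against a random pick from the same batches.
#'
#' The target-disease draws are constructed from a random stream that does
#' not depend on `rho`, so the target RRR is identical across `rho` values
#' at a fixed seed.
#'
#' @param p A [pleiotropy_scenario()].
#' @param chunk_size Couples per chunk (memory cap).
#' @return A list of class `"pes_pleiotropy"` with elements `rrr_target`,
#'   `rri_correlated` (relative risk *increase* of the correlated disease;
#'   positive when selection raises its risk), their standard errors, and
#'   the component risks.
#' @examples
#' p <- pleiotropy_scenario(rho = -0.3, K1 = 0.05, K2 = 0.05,
#'                          r2_1 = 0.1, r2_2 = 0.1, n = 5,
#'                          n_couples = 1e5, seed = 1)
#' simulate_pleiotropy(p)
#' @export
simulate_pleiotropy <- function(p, chunk_size = 1e5) {
  stopifnot(inherits(p, "pes_pleiotropy_scenario"))
  z1 <- liability_threshold(p$K1)
  z2 <- liability_threshold(p$K2)
  s1 <- sqrt(p$r2_1 / 2)
  s2 <- sqrt(p$r2_2 / 2)
  cv <- p$rho * sqrt(p$r2_1 * p$r2_2) / 2
  # conditional coefficients: comp2 = a * z1 + b * z2 (z iid standard)
  a <- if (s1 > 0) cv / s1 else 0
  b <- sqrt(max(s2^2 - a^2, 0))
  n <- p$n

  .with_seed(p$seed, {
    acc <- c(sel1 = 0, sel2 = 0, rnd1 = 0, rnd2 = 0)
    done <- 0
    while (done < p$n_couples) {
      B <- min(chunk_size, p$n_couples - done)
      # disease-1 stream first and with rho-independent counts
      Z1c <- stats::rnorm(B)
      Z1x <- matrix(stats::rnorm(B * n), B, n)
      E1 <- matrix(stats::rnorm(B * n, sd = sqrt(1 - p$r2_1)), B, n)
      rnd <- sample.int(n, B, replace = TRUE)
      Z2c <- stats::rnorm(B)
      Z2x <- matrix(stats::rnorm(B * n), B, n)
      E2 <- matrix(stats::rnorm(B * n, sd = sqrt(1 - p$r2_2)), B, n)

      S1 <- s1 * Z1x + s1 * Z1c
      S2 <- (a * Z1x + b * Z2x) + (a * Z1c + b * Z2c)
      pick <- max.col(-S1, ties.method = "first")
      i <- seq_len(B)
      Y1 <- S1 + E1; Y2 <- S2 + E2
      acc["sel1"] <- acc["sel1"] + sum(Y1[cbind(i, pick)] > z1)
      acc["sel2"] <- acc["sel2"] + sum(Y2[cbind(i, pick)] > z2)
      acc["rnd1"] <- acc["rnd1"] + sum(Y1[cbind(i, rnd)] > z1)
      acc["rnd2"] <- acc["rnd2"] + sum(Y2[cbind(i, rnd)] > z2)
      done <- done + B
    }
    pr <- acc / p$n_couples
    se <- sqrt(pr * (1 - pr) / p$n_couples)
    rrr_t <- 1 - pr[["sel1"]] / pr[["rnd1"]]
    rri_c <- pr[["sel2"]] / pr[["rnd2"]] - 1
    # delta-method SEs for the ratios (arms treated as independent)
    se_rrr <- (pr[["sel1"]] / pr[["rnd1"]]) *
      sqrt((se[["sel1"]] / pr[["sel1"]])^2 + (se[["rnd1"]] / pr[["rnd1"]])^2)
    se_rri <- (pr[["sel2"]] / pr[["rnd2"]]) *
      sqrt((se[["sel2"]] / pr[["sel2"]])^2 + (se[["rnd2"]] / pr[["rnd2"]])^2)
    structure(list(rrr_target = rrr_t, rri_correlated = rri_c,
                   se_rrr_target = se_rrr, se_rri_correlated = se_rri,
                   p_target_selected = pr[["sel1"]],
                   p_target_random = pr[["rnd1"]],
                   p_correlated_selected = pr[["sel2"]],
                   p_correlated_random = pr[["rnd2"]],
                   scenario = p),
              class = "pes_pleiotropy")
  })
}

#' @export
print.pes_pleiotropy <- function(x, ...) {
  cat("Pleiotropy simulation (lowest-risk prioritization on the target)\n")
  cat(sprintf("  rho = %g, n = %d, couples = %d\n",
              x$scenario$rho, x$scenario$n, x$scenario$n_couples))
  cat(sprintf("  target RRR            : %.1f%% (SE %.2f)\n",
              100 * x$rrr_target, 100 * x$se_rrr_target))
  cat(sprintf("  correlated risk change: %+.1f%% (SE %.2f)\n",
              100 * x$rri_correlated, 100 * x$se_rri_correlated))
  invisible(x)
}
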