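# Polygenic scoring, ascertainment-corrected logistic risk, liability-scale
# conversion, and the empirical risk-reduction pipeline.

#' Compute additive polygenic scores
#'
#' Scores are the weighted sum of effect-allele dosages,
#' \eqn{\sum_j w_j d_j}, over the score-model variants that match the
#' genotypes by variant id.  Score-model entries whose id is absent, or
#' whose effect allele matches neither the ref nor the alt allele, are
#' reported with a warning (an error if nothing matches), never silently
#' dropped.  With `average = TRUE` the sum is divided by the number of
#' scored alleles (`2 *` matched variants), the per-allele mean applied by
#' common scoring tools; relative risk reductions are invariant to this
#' affine rescaling.
#'
#' @param genotypes A [phased_cohort()], a `"pes_embryos"` object, or a
#'   dosage matrix (samples x variants, columns named by variant id; pair
#'   it with a `variants` attribute or the `variants` argument).
#' @param model A score model data frame (`id`, `effect_allele`, `weight`).
#' @param average Return the per-allele average instead of the raw sum.
#' @param variants Variant table (`id`, `ref`, `alt`) when `genotypes` is
#'   a bare matrix.
#' @return Numeric vector of scores, one per sample/embryo.
#' @export
compute_prs <- function(genotypes, model, average = FALSE, variants = NULL) {
  if (inherits(genotypes, "phased_cohort")) {
    dos <- .dosages(genotypes); variants <- genotypes$variants
  } else if (inherits(genotypes, "pes_embryos")) {
    dos <- genotypes$h1 + genotypes$h2; variants <- genotypes$variants
  } else if (is.matrix(genotypes)) {
    dos <- genotypes
    if (is.null(variants)) stop("'variants' is required for a bare dosage matrix",
                                call. = FALSE)
  } else stop("unsupported genotype container", call. = FALSE)
  stopifnot(all(c("id", "effect_allele", "weight") %in% names(model)))

  vi <- match(model$id, variants$id)
  found <- !is.na(vi)
  ea_ok <- rep(FALSE, nrow(model))
  ea_ok[found] <- model$effect_allele[found] == variants$alt[vi[found]] |
    model$effect_allele[found] == variants$ref[vi[found]]
  usable <- found & ea_ok
  if (!any(usable))
    stop("no score variants could be matched to the genotypes", call. = FALSE)
  if (any(!usable))
    warning(sprintf("%d score variant(s) unmatched (missing id or effect allele not in {ref, alt})",
                    sum(!usable)))
  vi <- vi[usable]
  w <- model$weight[usable]
  flip <- model$effect_allele[usable] == variants$ref[vi]
  d <- dos[, vi, drop = FALSE]
  if (any(flip)) d[, flip] <- 2 - d[, flip]
  score <- as.vector(d %*% w)
  if (average) score <- score / (2 * length(w))
  score
}

#' Fit the case-control logistic risk model with intercept adjustment
#'
#' Maximum-likelihood logistic regression of case/control status on the
#' polygenic score (no covariates).  Because cases are oversampled
#' relative to the population prevalence, the sample intercept is adjusted
#' to the population scale:
#' \eqn{\beta_0^{adj} = \beta_0 - \log\frac{P(1-K)}{(1-P)K}}
#' where `P` is the sample case fraction and `K` the prevalence.
#' `predict()` on the returned object gives population-scale disease
#' probabilities.
#'
#' @param scores Numeric vector of polygenic scores.
#' @param statuses `"case"`/`"control"` character vector, or 0/1, or
#'   logical (case = `TRUE`/1).
#' @param K Population prevalence.
#' @return An object of class `"pes_logistic_risk"`.
#' @export
fit_logistic_risk <- function(scores, statuses, K) {
  .check_fraction(K, "K", lo_open = TRUE, hi_open = TRUE)
  y <- .as_case01(statuses)
  stopifnot(length(y) == length(scores))
  if (!any(y == 1) || !any(y == 0))
    stop("both cases and controls are required", call. = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ scores, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || abs(stats::coef(fit)[2]) > 1e3)
    stop("perfect separation: the logistic risk model is not identifiable",
         call. = FALSE)
  P <- mean(y)
  b0 <- unname(stats::coef(fit)[1])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept_sample = b0,
                 intercept_adjusted = b0 - log((P / (1 - P)) * ((1 - K) / K)),
                 K = K, sample_case_fraction = P),
            class = "pes_logistic_risk")
}

.as_case01 <- function(statuses) {
  if (is.character(statuses)) {
    if (!all(statuses %in% c("case", "control")))
      stop("character statuses must be 'case'/'control'", call. = FALSE)
    as.integer(statuses == "case")
  } else as.integer(as.logical(statuses))
}

#' @export
predict.pes_logistic_risk <- function(object, scores, scale = c("population", "sample"), ...) {
  scale <- match.arg(scale)
  b0 <- if (scale == "population") object$intercept_adjusted
        else object$intercept_sample
  stats::plogis(b0 + object$slope * scores)
}

#' @export
coef.pes_logistic_risk <- function(object, ...) {
  c(intercept_sample = object$intercept_sample,
    intercept_adjusted = object$intercept_adjusted,
    slope = object$slope)
}

#' @export
print.pes_logistic_risk <- function(x, ...) {
  cat("Logistic disease-risk model (score only)\n")
  cat(sprintf("  slope: %.4g  intercept (sample): %.4g  (population-adjusted): %.4g\n",
              x$slope, x$intercept_sample, x$intercept_adjusted))
  cat(sprintf("  prevalence K = %g, sample case fraction = %.3f\n",
              x$K, x$sample_case_fraction))
  invisible(x)
}

#' Prevalence-weighted normal reference for score percentiles
#'
#' Approximates the population distribution of the polygenic score by a
#' normal fitted to the case-control sample with cases weighted
#' proportional to `K / case fraction` and controls to
#' `(1 - K) / control fraction`, undoing the ascertainment.
#'
#' @inheritParams fit_logistic_risk
#' @return Named vector `c(mean, variance)` of the reference normal.
#' @export
calibrate_score_percentiles <- function(scores, statuses, K) {
  .check_fraction(K, "K")
  y <- .as_case01(statuses)
  if (stats::var(scores) == 0)
    stop("scores have zero variance; cannot calibrate percentiles",
         call. = FALSE)
  P <- mean(y)
  w <- ifelse(y == 1, if (P > 0) K / P else 0,
              if (P < 1) (1 - K) / (1 - P) else 0)
  c(mean = .wtd_mean(scores, w), variance = .wtd_var(scores, w))
}

#' Convert observed-scale case-control R2 to the liability scale
#'
#' Ascertainment-corrected transformation of the squared correlation
#' between case/control status and the score into the proportion of
#' liability variance explained (Lee et al. 2012, Genetic Epidemiology,
#' Eq. 15): with \eqn{z = \phi(z_K)}, \eqn{i = z/K},
#' \eqn{C = K^2(1-K)^2 / (z^2 P(1-P))} and
#' \eqn{\theta = i\frac{P-K}{1-K}\left(i\frac{P-K}{1-K} - z_K\right)},
#' \deqn{r^2_{liab} = \frac{C\, r^2_{obs}}{1 + C\,\theta\, r^2_{obs}}.}
#'
#' @param r2_observed Squared status-score correlation on the observed
#'   scale, in \[0, 1).
#' @param K Population prevalence.
#' @param sample_case_fraction Case fraction `P` in the sample.
#' @return Liability-scale variance explained, in \[0, 1).
#' @export
observed_to_liability_r2 <- function(r2_observed, K, sample_case_fraction) {
  .check_fraction(r2_observed, "r2_observed", hi_open = TRUE)
  .check_fraction(K, "K", lo_open = TRUE, hi_open = TRUE)
  .check_fraction(sample_case_fraction, "sample_case_fraction",
                  lo_open = TRUE, hi_open = TRUE)
  if (r2_observed == 0) return(0)
  zK <- liability_threshold(K)
  z <- stats::dnorm(zK)
  i <- z / K
  P <- sample_case_fraction
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  theta <- i * (P - K) / (1 - K) * (i * (P - K) / (1 - K) - zK)
  out <- C * r2_observed / (1 + C * theta * r2_observed)
  if (!is.finite(out) || out < 0 || out >= 1)
    stop("liability-scale r2 out of range; check K and the case fraction",
         call. = FALSE)
  out
}

#' Empirical risk reduction over simulated embryo batches
#'
#' Given per-couple embryo scores and a fitted risk model, selects one
#' embryo per couple by the given strategy and one uniformly at random,
#' predicts population-scale disease probabilities for both, and averages
#' over couples.
#'
#' @param embryo_scores Matrix of embryo polygenic scores, one row per
#'   couple; at least `n_embryos_used` columns.
#' @param risk_model A [fit_logistic_risk()] result.
#' @param strategy `"lrp"` or `"hre"`.
#' @param n_embryos_used Embryos considered per couple.
#' @param percentile_ref Named vector `c(mean, variance)` from
#'   [calibrate_score_percentiles()]; required for HRE.
#' @param q High-risk fraction for HRE (top-`q` of the reference normal).
#' @param seed Integer seed for the random picks.
#' @return A `"pes_risk"` object (baseline = random selection).
#' @export
empirical_rrr <- function(embryo_scores, risk_model, strategy = c("lrp", "hre"),
                          n_embryos_used, percentile_ref = NULL, q = 0.02,
                          seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(is.matrix(embryo_scores), inherits(risk_model, "pes_logistic_risk"),
            n_embryos_used >= 1, ncol(embryo_scores) >= n_embryos_used)
  S <- embryo_scores[, seq_len(n_embryos_used), drop = FALSE]
  n <- ncol(S)
  .with_seed(seed, {
    if (strategy == "lrp") {
      pick <- max.col(-S, ties.method = "first")
    } else {
      if (is.null(percentile_ref))
        stop("HRE requires 'percentile_ref'", call. = FALSE)
      thr <- stats::qnorm(1 - q, mean = percentile_ref[["mean"]],
                          sd = sqrt(percentile_ref[["variance"]]))
      pick <- .select_index(S, "hre", thr)
    }
    rnd <- if (n == 1L) rep(1L, nrow(S)) else sample.int(n, nrow(S), replace = TRUE)
    i <- seq_len(nrow(S))
    p_sel <- mean(predict(risk_model, S[cbind(i, pick)]))
    p_rnd <- mean(predict(risk_model, S[cbind(i, rnd)]))
    risk_metrics(p_rnd, p_sel)
  })
}

#' Within-couple embryo score variance diagnostics
#'
#' Under the infinitesimal model the variance of embryo scores within a
#' couple is half the score variance in the parental population and does
#' not depend on the mean parental score.  This computes the per-couple
#' variances, their pooled mean, the regression slope of variance on mean
#' parental score (flatness check), and -- when `parental_variance` is
#' supplied -- the pooled-to-parental variance ratio (expected ~0.5).
#'
#' @param parent_mean_scores Mean parental score per couple.
#' @param embryo_scores Embryo score matrix (couples x embryos, >= 2
#'   embryos).
#' @param parental_variance Optional population variance of the parental
#'   scores (e.g. from [calibrate_score_percentiles()]).
#' @return A list of class `"pes_embryo_diag"`: `table` (per-couple data
#'   frame), `pooled_variance`, `slope`, `variance_ratio`.
#' @export
embryo_variance_diagnostics <- function(parent_mean_scores, embryo_scores,
                                        parental_variance = NULL) {
  stopifnot(is.matrix(embryo_scores), ncol(embryo_scores) >= 2,
            length(parent_mean_scores) == nrow(embryo_scores))
  v <- apply(embryo_scores, 1, stats::var)
  fit <- stats::lm(v ~ parent_mean_scores)
  out <- list(table = data.frame(mean_parental = parent_mean_scores,
                                 var_embryo = v),
              pooled_variance = mean(v),
              slope = unname(stats::coef(fit)[2]),
              variance_ratio = if (!is.null(parental_variance))
                mean(v) / parental_variance else NA_real_)
  class(out) <- "pes_embryo_diag"
  out
}

#' @export
print.pes_embryo_diag <- function(x, ...) {
  cat("Embryo score variance diagnostics\n")
  cat(sprintf("  pooled within-couple variance : %.4g\n", x$pooled_variance))
  if (is.finite(x$variance_ratio))
    cat(sprintf("  ratio to parental variance    : %.3f (expected ~0.5)\n",
                x$variance_ratio))
  cat(sprintf("  slope vs mean parental score  : %.4g (expected ~0)\n", x$slope))
  invisible(x)
}

#' Genome-level screening experiment on a synthetic cohort
#'
#' End-to-end validation pipeline: generate (or accept) a synthetic phased
#' case-control cohort, fit the ascertainment-corrected logistic risk
#' model and the prevalence-weighted percentile reference on the parents,
#' convert the observed-scale score-status correlation to the liability
#' scale, form virtual couples, simulate embryos by Mendelian segregation
#' with map-based Poisson recombination, score them, and measure the
#' empirical risk reduction under both strategies against the
#' liability-threshold-model theory.
#'
#' @param n_cases,n_controls,n_variants,n_chromosomes,maf_range,target_r2_liab,K
#'   Passed to [generate_synthetic_cohort()].
#' @param n_couples Virtual couples to form.
#' @param n_embryos Embryos simulated per couple.
#' @param n_embryos_used Embryos considered by the selection strategies
#'   (defaults to all simulated embryos; simulating more than are used
#'   sharpens the within-couple variance diagnostics).
#' @param q High-risk fraction for the HRE arm.
#' @param seed Integer master seed for the whole pipeline.
#' @param synth Optionally a pre-built list (`cohort`, `map`, `score`) to
#'   use instead of generating one.
#' @return A list of class `"pes_genome_experiment"` with the fitted
#'   models, the Lee-converted `r2_liab`, empirical and theoretical risk
#'   results per strategy, and the variance diagnostics.
#' @export
run_genome_experiment <- function(n_cases = 300, n_controls = 300,
                                  n_variants = 600, n_chromosomes = 4,
                                  maf_range = c(0.1, 0.5),
                                  target_r2_liab = 0.07, K = 0.01,
                                  n_couples = 1000, n_embryos = 5,
                                  n_embryos_used = n_embryos,
                                  q = 0.02, seed = 1, synth = NULL) {
  stopifnot(n_embryos_used <= n_embryos)
  if (is.null(synth))
    synth <- generate_synthetic_cohort(n_cases, n_controls, n_variants,
                                       n_chromosomes, maf_range,
                                       target_r2_liab, K, seed = seed)
  cohort <- synth$cohort; map <- synth$map; score <- synth$score

  parent_scores <- compute_prs(cohort, score)
  y <- .as_case01(cohort$samples$status)
  risk_model <- fit_logistic_risk(parent_scores, y, K)
  pref <- calibrate_score_percentiles(parent_scores, y, K)
  r2_obs <- stats::cor(y, parent_scores)^2
  r2_liab <- observed_to_liability_r2(r2_obs, K, mean(y))

  couples <- mate_virtual_couples(cohort, n_couples, K, seed = seed + 1)

  # simulate and score embryos couple by couple (one RNG stream);
  # the map index and score-variant matching are resolved once
  idx <- .map_index(cohort$variants, map)
  vi <- match(score$id, cohort$variants$id)
  w <- score$weight
  flip <- score$effect_allele == cohort$variants$ref[vi]
  embryo_scores <- .with_seed(seed + 2, {
    t(vapply(seq_len(nrow(couples)), function(i) {
      p1 <- get_genome(cohort, couples$parent1[i])
      p2 <- get_genome(cohort, couples$parent2[i])
      emb <- .simulate_offspring_impl(p1, p2, map, n_embryos, idx = idx)
      d <- (emb$h1 + emb$h2)[, vi, drop = FALSE]
      if (any(flip)) d[, flip] <- 2 - d[, flip]
      as.vector(d %*% w)
    }, numeric(n_embryos)))
  })
  parent_mean <- (parent_scores[couples$parent1] +
                    parent_scores[couples$parent2]) / 2

  res_lrp <- empirical_rrr(embryo_scores, risk_model, "lrp", n_embryos_used,
                           seed = seed + 3)
  res_hre <- empirical_rrr(embryo_scores, risk_model, "hre", n_embryos_used,
                           percentile_ref = pref, q = q, seed = seed + 4)
  theory_lrp <- analytic_risk(pes_scenario(K, r2_liab, n_embryos_used, "lrp"))
  theory_hre <- analytic_risk(pes_scenario(K, r2_liab, n_embryos_used, "hre",
                                           q = q))
  diag <- embryo_variance_diagnostics(parent_mean, embryo_scores,
                                      parental_variance = pref[["variance"]])

  structure(list(cohort = cohort, map = map, score = score,
                 risk_model = risk_model, percentile_ref = pref,
                 r2_observed = r2_obs, r2_liab = r2_liab,
                 couples = couples, embryo_scores = embryo_scores,
                 empirical = list(lrp = res_lrp, hre = res_hre),
                 theory = list(lrp = theory_lrp, hre = theory_hre),
                 diagnostics = diag, K = K, n_embryos = n_embryos,
                 n_embryos_used = n_embryos_used, q = q,
                 seed = seed),
            class = "pes_genome_experiment")
}

#' @export
print.pes_genome_experiment <- function(x, ...) {
  cat("Genome-level screening experiment (synthetic cohort)\n")
  cat(sprintf("  cohort: %d samples, %d variants; K = %g\n",
              nrow(x$cohort$samples), nrow(x$cohort$variants), x$K))
  cat(sprintf("  liability-scale r2 (Lee): %.4f\n", x$r2_liab))
  cat(sprintf("  LRP  empirical RRR %.1f%%  vs theory %.1f%%\n",
              100 * x$empirical$lrp$rrr, 100 * x$theory$lrp$rrr))
  cat(sprintf("  HRE  empirical RRR %.1f%%  vs theory %.1f%%\n",
              100 * x$empirical$hre$rrr, 100 * x$theory$hre$rrr))
  cat(sprintf("  embryo/parental variance ratio: %.3f\n",
              x$diagnostics$variance_ratio))
  invisible(x)
}
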