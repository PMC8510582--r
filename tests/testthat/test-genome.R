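make_small_synth <- function(seed = 1) {
  generate_synthetic_cohort(n_cases = 40, n_controls = 40, n_variants = 60,
                            n_chromosomes = 3, target_r2_liab = 0.1,
                            K = 0.2, seed = seed)
}

test_that("the synthetic cohort generator is deterministic and sized as requested", {
  a <- make_small_synth(5)
  b <- make_small_synth(5)
  expect_identical(a$cohort$h1, b$cohort$h1)
  expect_identical(a$score$weight, b$score$weight)
  expect_identical(table(a$cohort$samples$status),
                   table(c(rep("case", 40), rep("control", 40))))
  d <- make_small_synth(6)
  expect_false(identical(a$cohort$h1, d$cohort$h1))
})

test_that("the generator's score recovers the target liability r2 through the Lee conversion", {
  syn <- generate_synthetic_cohort(n_cases = 500, n_controls = 500,
                                   n_variants = 400, n_chromosomes = 4,
                                   target_r2_liab = 0.1, K = 0.05, seed = 7)
  sc <- compute_prs(syn$cohort, syn$score)
  y <- as.integer(syn$cohort$samples$status == "case")
  r2_liab <- observed_to_liability_r2(cor(y, sc)^2, 0.05, mean(y))
  expect_lt(abs(r2_liab - 0.1) / 0.1, 0.20)   # within 20% relative
})

test_that("virtual couples match the random-mating status composition", {
  syn <- make_small_synth(2)
  expect_warning(cp <- mate_virtual_couples(syn$cohort, 500, K = 0.2, seed = 3),
                 "reused across couples")
  expect_equal(nrow(cp), 500)
  n_cc <- sum(cp$status1 == "control" & cp$status2 == "control")
  n_aa <- sum(cp$status1 == "case" & cp$status2 == "case")
  expect_equal(n_cc, round(0.8^2 * 500), tolerance = 1)
  expect_equal(n_aa, round(0.2^2 * 500), tolerance = 1)
  expect_equal(n_cc + n_aa + sum(cp$status1 != cp$status2), 500)
  # couples are distinct unordered pairs with distinct members
  expect_true(all(cp$parent1 != cp$parent2))
  key <- paste(pmin(cp$parent1, cp$parent2), pmax(cp$parent1, cp$parent2))
  expect_false(any(duplicated(key)))
  # K = 0: all couples control-control
  cp0 <- suppressWarnings(mate_virtual_couples(syn$cohort, 50, K = 0, seed = 3))
  expect_true(all(cp0$status1 == "control" & cp0$status2 == "control"))
})

test_that("couple formation refuses impossible compositions", {
  syn <- make_small_synth(2)
  only_ctrl <- syn$cohort
  only_ctrl$samples$status <- rep("control", nrow(only_ctrl$samples))
  expect_error(mate_virtual_couples(only_ctrl, 100, K = 0.2, seed = 1),
               "insufficient cases")
})

test_that("embryos satisfy the Mendelian constraint at every site", {
  syn <- make_small_synth(3)
  p1 <- get_genome(syn$cohort, 1)
  p2 <- get_genome(syn$cohort, 2)
  emb <- simulate_offspring(p1, p2, syn$map, n_embryos = 8, seed = 4)
  for (e in 1:8) {
    expect_true(all(emb$h1[e, ] == p1$h1 | emb$h1[e, ] == p1$h2))
    expect_true(all(emb$h2[e, ] == p2$h1 | emb$h2[e, ] == p2$h2))
  }
  # determinism
  emb2 <- simulate_offspring(p1, p2, syn$map, n_embryos = 8, seed = 4)
  expect_identical(emb$h1, emb2$h1)
})

test_that("a zero-length chromosome transmits an intact parental strand", {
  variants <- data.frame(chrom = 1, pos = seq(1e5, 1e6, by = 1e5),
                         id = paste0("v", 1:10), ref = "A", alt = "G")
  map0 <- data.frame(chrom = 1, bp = c(0, 2e6), cM = c(0, 0))
  p1 <- list(h1 = rep(0L, 10), h2 = rep(1L, 10), variants = variants)
  emb <- simulate_offspring(p1, p1, map0, n_embryos = 20, seed = 5)
  for (e in 1:20) {
    expect_true(all(emb$h1[e, ] == 0L) || all(emb$h1[e, ] == 1L))
    expect_true(all(emb$h2[e, ] == 0L) || all(emb$h2[e, ] == 1L))
  }
})

test_that("crossover counts on a 1-Morgan chromosome are Poisson with mean 1", {
  m <- 201
  variants <- data.frame(chrom = 1, pos = seq(1, 100e6, length.out = m),
                         id = paste0("v", 1:m), ref = "A", alt = "G")
  map1 <- data.frame(chrom = 1, bp = c(0, 100e6), cM = c(0, 100))
  # distinguishable strands so every strand switch is visible
  p1 <- list(h1 = rep(0L, m), h2 = rep(1L, m), variants = variants)
  emb <- simulate_offspring(p1, p1, map1, n_embryos = 5000, seed = 6)
  switches <- function(H) rowSums(H[, -1, drop = FALSE] != H[, -m, drop = FALSE])
  cx <- c(switches(emb$h1), switches(emb$h2))     # 10^4 meioses
  expect_lt(abs(mean(cx) - 1), 3 * sqrt(1 / length(cx)))
  # distribution shape: chi-square against Poisson(1) on bins 0,1,2,>=3
  obs <- c(sum(cx == 0), sum(cx == 1), sum(cx == 2), sum(cx >= 3))
  expected <- c(dpois(0:2, 1), ppois(2, 1, lower.tail = FALSE))
  pval <- chisq.test(obs, p = expected)$p.value
  expect_gt(pval, 0.01)
})

test_that("simulation refuses variants outside the genetic map", {
  variants <- data.frame(chrom = 1, pos = c(10, 50, 99), id = paste0("v", 1:3),
                         ref = "A", alt = "G")
  short_map <- data.frame(chrom = 1, bp = c(20, 60), cM = c(0, 1))
  p <- list(h1 = c(0L, 0L, 0L), h2 = c(1L, 1L, 1L), variants = variants)
  expect_error(simulate_offspring(p, p, short_map, 1, seed = 1),
               "outside genetic map")
})

test_that("polygenic scores are exact weighted allele-dosage sums", {
  variants <- data.frame(chrom = 1, pos = c(100, 200, 300),
                         id = c("a", "b", "c"), ref = c("A", "C", "A"),
                         alt = c("G", "T", "G"))
  # two samples: dosages of the alt allele
  dos <- rbind(s1 = c(0, 1, 2), s2 = c(2, 0, 1))
  model <- data.frame(id = c("a", "b", "c"), effect_allele = c("G", "T", "A"),
                      weight = c(0.5, -1, 2))
  # hand computation: for variant c the effect allele is the ref, dosage 2-d
  expect_equal(compute_prs(dos, model, variants = variants),
               c(0 * 0.5 + 1 * -1 + (2 - 2) * 2,
                 2 * 0.5 + 0 * -1 + (2 - 1) * 2))
  # per-allele average dialect: affine rescaling by 1/(2m)
  expect_equal(compute_prs(dos, model, variants = variants, average = TRUE),
               compute_prs(dos, model, variants = variants) / 6)
  # zero weights, zero score; heterozygote single-variant contribution
  expect_equal(compute_prs(dos, transform(model, weight = 0),
                           variants = variants), c(0, 0))
  one <- data.frame(id = "b", effect_allele = "T", weight = 0.7)
  expect_equal(compute_prs(dos, one, variants = variants), c(0.7, 0))
})

test_that("unmatched score variants are reported, never silently dropped", {
  variants <- data.frame(chrom = 1, pos = 1:2, id = c("a", "b"),
                         ref = "A", alt = "G")
  dos <- matrix(c(1, 2), 1)
  model <- data.frame(id = c("a", "zzz"), effect_allele = c("G", "G"),
                      weight = c(1, 1))
  expect_warning(s <- compute_prs(dos, model, variants = variants),
                 "1 score variant")
  expect_equal(s, 1)
  bad_allele <- data.frame(id = "a", effect_allele = "T", weight = 1)
  expect_error(suppressWarnings(compute_prs(dos, bad_allele, variants = variants)),
               "no score variants")
})

test_that("logistic risk intercept adjustment undoes case oversampling", {
  set.seed(9)
  # balanced sample with K equal to the sample fraction: no adjustment
  sc <- rnorm(400)
  y <- rbinom(400, 1, plogis(-0.2 + 0.8 * sc))
  fit <- fit_logistic_risk(sc, y, K = mean(y))
  expect_equal(fit$intercept_adjusted, fit$intercept_sample, tolerance = 1e-10)

  # shuffled labels: slope ~ 0, predictions ~ K everywhere after adjustment
  yperm <- sample(rep(0:1, each = 200))
  fit2 <- fit_logistic_risk(sc, yperm, K = 0.03)
  preds <- predict(fit2, seq(-2, 2, by = 0.5))
  expect_true(all(abs(preds - 0.03) < 0.015))

  # mean adjusted risk over a population-representative score sample ~ K
  K <- 0.1
  sc_big <- rnorm(4000)
  yc <- as.integer(0.5 * sc_big + rnorm(4000, 0, sqrt(1 - 0.25)) > qnorm(1 - K))
  fit3 <- fit_logistic_risk(sc_big, yc, K = K)
  pop_sc <- rnorm(2e4)
  expect_equal(mean(predict(fit3, pop_sc)), K, tolerance = 0.02)
})

test_that("perfect separation is reported as such", {
  sc <- c(-(5:1), 1:5)
  y <- c(rep(0, 5), rep(1, 5))
  expect_error(fit_logistic_risk(sc, y, K = 0.1), "separation")
})

test_that("prevalence-weighted score calibration matches hand computation", {
  scores <- c(1, 3, 2, 6)
  status <- c("control", "control", "case", "case")
  K <- 0.1
  w <- c(0.9 / 0.5, 0.9 / 0.5, 0.1 / 0.5, 0.1 / 0.5)
  m_hand <- sum(w * scores) / sum(w)
  wn <- w * 4 / sum(w)
  v_hand <- sum(wn * (scores - m_hand)^2) / 3
  cal <- calibrate_score_percentiles(scores, status, K)
  expect_equal(cal[["mean"]], m_hand, tolerance = 1e-12)
  expect_equal(cal[["variance"]], v_hand, tolerance = 1e-12)

  # identically distributed scores in cases and controls: weighting is a no-op
  cal2 <- calibrate_score_percentiles(c(1, 2, 1, 2),
                                      c("case", "case", "control", "control"),
                                      K = 0.3)
  expect_equal(cal2[["mean"]], 1.5)
  expect_equal(cal2[["variance"]], var(c(1, 2, 1, 2)), tolerance = 1e-12)
  expect_error(calibrate_score_percentiles(rep(1, 4), status, K), "variance")
})

test_that("the liability-scale conversion is anchored and monotone", {
  expect_identical(observed_to_liability_r2(0, 0.05, 0.5), 0)
  r2s <- seq(0.01, 0.3, by = 0.02)
  out <- vapply(r2s, observed_to_liability_r2, 0, K = 0.05,
                sample_case_fraction = 0.5)
  expect_true(all(diff(out) > 0))
  expect_true(all(out > 0 & out < 1))
})

test_that("cohort, map and score files round-trip through their text formats", {
  syn <- make_small_synth(8)
  vcf <- tempfile(fileext = ".vcf")
  write_cohort_vcf(syn$cohort, vcf)
  back <- read_phased_cohort(vcf, statuses = setNames(syn$cohort$samples$status,
                                                      syn$cohort$samples$id))
  expect_identical(back$h1, unname(syn$cohort$h1))
  expect_identical(back$h2, unname(syn$cohort$h2))
  expect_equal(back$variants$pos, syn$cohort$variants$pos)
  expect_identical(back$samples$status, syn$cohort$samples$status)

  mf <- tempfile(fileext = ".map")
  write_genetic_map(syn$map, mf)
  map2 <- read_genetic_map(mf)
  expect_equal(map2$cM, syn$map$cM)

  sf <- tempfile(fileext = ".score")
  write_score_model(syn$score, sf)
  sc2 <- read_score_model(sf)
  expect_equal(sc2$weight, syn$score$weight, tolerance = 1e-12)
  expect_identical(sc2$id, syn$score$id)
})

test_that("unphased VCF genotypes are rejected", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(read_phased_cohort(vcf, statuses = c(S1 = "case")), "phased")
})

test_that("empirical risk reduction is zero with one embryo and HRE needs a reference", {
  syn <- make_small_synth(9)
  sc <- compute_prs(syn$cohort, syn$score)
  y <- syn$cohort$samples$status
  fit <- fit_logistic_risk(sc, y, K = 0.2)
  S <- matrix(rnorm(200, sd = sd(sc)), 40, 5)
  r1 <- empirical_rrr(S, fit, "lrp", n_embryos_used = 1, seed = 2)
  expect_equal(r1$rrr, 0, tolerance = 1e-12)
  expect_error(empirical_rrr(S, fit, "hre", 5, percentile_ref = NULL),
               "percentile_ref")
})

test_that("identical homozygous parents give zero embryo score variance", {
  m <- 10
  variants <- data.frame(chrom = 1, pos = seq(1e5, 1e6, length.out = m),
                         id = paste0("v", 1:m), ref = "A", alt = "G")
  map1 <- data.frame(chrom = 1, bp = c(0, 2e6), cM = c(0, 2))
  p <- list(h1 = rep(1L, m), h2 = rep(1L, m), variants = variants)
  emb <- simulate_offspring(p, p, map1, n_embryos = 6, seed = 3)
  model <- data.frame(id = variants$id, effect_allele = "G",
                      weight = runif(m))
  s <- compute_prs(emb, model)
  d <- embryo_variance_diagnostics(sum(2 * model$weight),
                                   matrix(s, nrow = 1))
  expect_equal(d$pooled_variance, 0)
})

test_that("the genome pipeline is reproducible end to end from one seed", {
  a <- suppressWarnings(
    run_genome_experiment(n_cases = 60, n_controls = 60, n_variants = 120,
                          n_chromosomes = 2, target_r2_liab = 0.1,
                          K = 0.1, n_couples = 80, n_embryos = 3, seed = 12))
  b <- suppressWarnings(
    run_genome_experiment(n_cases = 60, n_controls = 60, n_variants = 120,
                          n_chromosomes = 2, target_r2_liab = 0.1,
                          K = 0.1, n_couples = 80, n_embryos = 3, seed = 12))
  expect_identical(a$embryo_scores, b$embryo_scores)
  expect_identical(a$empirical$lrp$rrr, b$empirical$lrp$rrr)
})
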