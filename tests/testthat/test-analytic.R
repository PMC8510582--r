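test_that("no selection (n = 1) or an uninformative score (r2 = 0) leaves risk at prevalence", {
  for (K in c(0.01, 0.2)) {
    expect_equal(risk_lrp(pes_scenario(K, 0.1, 1)), K, tolerance = 1e-8)
    expect_equal(risk_lrp(pes_scenario(K, 0, 5)), K, tolerance = 1e-12)
    expect_equal(risk_hre(pes_scenario(K, 0.1, 1, "hre", q = 0.02)), K,
                 tolerance = 1e-8)
  }
  r <- risk_given_c(pes_scenario(0.05, 0.1, 1), 0.2)
  expect_equal(r$rrr, 0, tolerance = 1e-10)
})

test_that("the two integral forms of the LRP risk agree", {
  # order-statistic density route vs conditioning on the residual
  for (par in list(c(0.01, 0.08, 5), c(0.05, 0.3, 2), c(0.2, 0.1, 10))) {
    scn <- pes_scenario(par[1], par[2], par[3])
    for (c0 in c(-0.3, 0, 0.4)) {
      expect_equal(pesrisk:::.risk_sel_given_c(c0, scn),
                   pesrisk:::.risk_lrp_given_c_alt(c0, scn),
                   tolerance = 1e-8)
    }
  }
})

test_that("the vectorized Gauss-Legendre LRP kernel matches the adaptive route", {
  scn <- pes_scenario(0.05, 0.1, 5)
  cg <- c(-0.5, -0.1, 0, 0.2, 0.6)
  expect_equal(pesrisk:::.risk_lrp_given_c_vec(cg, scn),
               vapply(cg, function(c0) pesrisk:::.risk_sel_given_c(c0, scn), 0),
               tolerance = 1e-8)
})

test_that("HRE boundary exclusion fractions recover prevalence and the fallback recovers LRP", {
  scn0 <- pes_scenario(0.05, 0.3, 5, "hre", q = 0)
  scn1 <- pes_scenario(0.05, 0.3, 5, "hre", q = 1)
  expect_equal(risk_hre(scn0), 0.05, tolerance = 1e-8)
  expect_equal(risk_hre(scn1), 0.05, tolerance = 1e-8)
  fb1 <- pes_scenario(0.05, 0.3, 5, "hre-fallback-lowest", q = 1)
  expect_equal(risk_hre_fallback_lowest(fb1),
               risk_lrp(pes_scenario(0.05, 0.3, 5)), tolerance = 1e-8)
  fb0 <- pes_scenario(0.05, 0.3, 5, "hre-fallback-lowest", q = 0)
  expect_equal(risk_hre_fallback_lowest(fb0), 0.05, tolerance = 1e-8)
})

test_that("strategies are ordered: LRP <= HRE-fallback <= HRE <= prevalence", {
  for (K in c(0.01, 0.2)) for (r2 in c(0.05, 0.3)) {
    lrp <- risk_lrp(pes_scenario(K, r2, 5))
    hre <- risk_hre(pes_scenario(K, r2, 5, "hre", q = 0.1))
    fb <- risk_hre_fallback_lowest(pes_scenario(K, r2, 5,
                                                "hre-fallback-lowest", q = 0.1))
    expect_lte(lrp, fb + 1e-9)
    expect_lte(fb, hre + 1e-9)
    expect_lte(hre, K + 1e-9)
  }
})

test_that("LRP risk decreases with embryo count and score strength; fallback decreases with q", {
  ns <- c(1, 2, 5, 10)
  ps <- vapply(ns, function(n) risk_lrp(pes_scenario(0.05, 0.1, n)), 0)
  expect_true(all(diff(ps) < 0))
  r2s <- c(0.02, 0.05, 0.1, 0.3)
  pr <- vapply(r2s, function(r2) risk_lrp(pes_scenario(0.05, r2, 5)), 0)
  expect_true(all(diff(pr) < 0))
  qs <- c(0.02, 0.1, 0.25, 0.5, 1)
  pq <- vapply(qs, function(q)
    risk_hre_fallback_lowest(pes_scenario(0.05, 0.1, 5,
                                          "hre-fallback-lowest", q = q)), 0)
  expect_true(all(diff(pq) < 1e-9))
})

test_that("conditional risks integrate back to the unconditional values", {
  for (strat in list(list("lrp", NULL), list("hre", 0.1))) {
    scn <- pes_scenario(0.05, 0.1, 5, strat[[1]], q = strat[[2]])
    sc <- sqrt(scn$r2 / 2)
    avg <- integrate(function(cv)
      vapply(cv, function(c0) pesrisk:::.risk_sel_given_c(c0, scn), 0) *
        dnorm(cv / sc) / sc, -8 * sc, 8 * sc, abs.tol = 1e-10)$value
    expect_equal(avg, pesrisk:::.risk_uncond(scn), tolerance = 1e-7)
  }
})

test_that("baseline given c has the closed form implied by the generative model", {
  scn <- pes_scenario(0.05, 0, 5)
  expect_equal(risk_random_given_c(scn, 0), 0.05, tolerance = 1e-12)
  # argument of the normal CDF zero -> risk one half
  scn2 <- pes_scenario(0.05, 0.1, 5)
  c_half <- liability_threshold(0.05)
  expect_equal(risk_random_given_c(scn2, c_half), 0.5, tolerance = 1e-12)
  # against Monte Carlo at a 90th-percentile couple
  c90 <- qnorm(0.9, sd = sqrt(0.1 / 2))
  set.seed(11)
  B <- 1e6
  y <- c90 + rnorm(B, 0, sqrt(0.1 / 2)) + rnorm(B, 0, sqrt(1 - 0.1))
  p_mc <- mean(y > liability_threshold(0.05))
  expect_lt(abs(risk_random_given_c(scn2, c90) - p_mc),
            3 * sqrt(p_mc * (1 - p_mc) / B))
})

test_that("selected-embryo risk given c matches the brute-force oracle", {
  scn <- pes_scenario(0.05, 0.1, 5)
  c_med <- 0
  orc <- mc_oracle_selection(0.05, 0.1, 5, "lrp", n_batches = 2e5,
                             c_fixed = c_med, seed = 5)
  r <- risk_given_c(scn, c_med)
  expect_lt(abs(r$p_disease - orc$p), 3 * orc$se)
})

test_that("per-couple curve is degenerate at n = 1 and consistent with the law of total probability", {
  pc1 <- pcrrr_distribution(pes_scenario(0.05, 0.1, 1), 100)
  expect_true(all(abs(pc1$pcrrr) < 1e-10))

  scn <- pes_scenario(0.05, 0.1, 5)
  pc <- pcrrr_distribution(scn, 1e4)
  expect_equal(sum(pc$weight * pc$p_selected), risk_lrp(scn), tolerance = 1e-3)
  expect_equal(sum(pc$weight * pc$p_random), scn$K, tolerance = 1e-3)
  # narrow distribution: spread below the mean pcRRR
  expect_lt(max(pc$pcrrr) - min(pc$pcrrr), mean(pc$pcrrr))
})

test_that("parental disease status shifts the baseline as the posterior implies", {
  scn <- pes_scenario(0.05, 0.1, 5)
  one_aff <- risk_given_parental_status(
    scn, pes_couple(h2 = 0.4, status1 = "affected", status2 = "unaffected"))
  expect_lt(abs(one_aff$p_baseline - 0.100), 0.002)
  expect_lt(abs(one_aff$p_disease - 0.058), 0.002)

  # no heritable signal: baseline collapses to prevalence
  h0 <- risk_given_parental_status(
    pes_scenario(0.05, 0, 5),
    pes_couple(h2 = 0, status1 = "affected", status2 = "affected"))
  expect_equal(h0$p_baseline, 0.05, tolerance = 1e-8)

  # unknown statuses marginalize back to the unconditional risk
  unk <- risk_given_parental_status(scn, pes_couple(h2 = 0.4))
  expect_equal(unk$p_baseline, scn$K, tolerance = 1e-4)
  expect_equal(unk$p_disease, risk_lrp(scn), tolerance = 1e-4)

  expect_error(risk_given_parental_status(
    pes_scenario(0.05, 0.5, 5),
    pes_couple(h2 = 0.4, status1 = "affected", status2 = "unaffected")), "h2")
})

test_that("healthy-parent conditioning matches a rejection-sampling oracle", {
  scn <- pes_scenario(0.05, 0.1, 1)
  cpl <- pes_couple(h2 = 0.4, status1 = "unaffected", status2 = "unaffected")
  res <- risk_given_parental_status(scn, cpl)
  expect_lt(res$p_baseline, scn$K)

  # simulate parental liabilities, keep unaffected couples, breed one child
  set.seed(31)
  zK <- liability_threshold(0.05); h2 <- 0.4; r2 <- 0.1
  M <- 4e5
  s1 <- rnorm(M, 0, sqrt(r2)); s2 <- rnorm(M, 0, sqrt(r2))
  g1 <- rnorm(M, 0, sqrt(h2 - r2)); g2 <- rnorm(M, 0, sqrt(h2 - r2))
  keep <- (s1 + g1 + rnorm(M, 0, sqrt(1 - h2)) <= zK) &
          (s2 + g2 + rnorm(M, 0, sqrt(1 - h2)) <= zK)
  n_k <- sum(keep)
  child <- (s1 + s2)[keep] / 2 + (g1 + g2)[keep] / 2 +
    rnorm(n_k, 0, sqrt(r2 / 2)) + rnorm(n_k, 0, sqrt((h2 - r2) / 2)) +
    rnorm(n_k, 0, sqrt(1 - h2))
  p_mc <- mean(child > zK)
  expect_lt(abs(res$p_baseline - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / n_k))
})

test_that("HRE risk conditional on parental status lies between LRP and the baseline", {
  cpl <- pes_couple(h2 = 0.4, status1 = "affected", status2 = "unaffected")
  hre <- risk_given_parental_status(
    pes_scenario(0.05, 0.1, 5, "hre", q = 0.1), cpl)
  lrp <- risk_given_parental_status(pes_scenario(0.05, 0.1, 5), cpl)
  expect_lte(lrp$p_disease, hre$p_disease + 1e-9)
  expect_lte(hre$p_disease, hre$p_baseline + 1e-9)
  expect_equal(hre$p_baseline, lrp$p_baseline, tolerance = 1e-10)
})
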