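# independent oracles used to freeze expected values

# inverse normal CDF by bisection on pnorm (independent of qnorm)
bisect_upper_quantile <- function(K, tol = 1e-12) {
  lo <- -20; hi <- 20
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pnorm(mid, lower.tail = FALSE) > K) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force batch simulator, structured differently from the package's
# vectorized engine (per-batch loop, explicit eligibility sets)
mc_oracle_selection <- function(K, r2, n, strategy = "lrp", q = NULL,
                                n_batches = 2e5, c_fixed = NULL, seed = 1) {
  zK <- qnorm(1 - K)
  thr <- if (!is.null(q)) qnorm(1 - q) * sqrt(r2) else NULL
  set.seed(seed)
  aff <- logical(n_batches)
  for (b in seq_len(n_batches)) {
    c0 <- if (is.null(c_fixed)) rnorm(1, 0, sqrt(r2 / 2)) else c_fixed
    s <- c0 + rnorm(n, 0, sqrt(r2 / 2))
    pick <- switch(strategy,
      lrp = which.min(s),
      hre = {
        el <- which(s < thr)
        if (length(el)) el[sample.int(length(el), 1)] else sample.int(n, 1)
      },
      `hre-fallback-lowest` = {
        el <- which(s < thr)
        if (length(el)) el[sample.int(length(el), 1)] else which.min(s)
      })
    aff[b] <- s[pick] + rnorm(1, 0, sqrt(1 - r2)) > zK
  }
  p <- mean(aff)
  list(p = p, se = sqrt(p * (1 - p) / n_batches))
}
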