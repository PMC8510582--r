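# internal numerical helpers

# Integration bounds are taken at +/- 8 SD; the neglected normal tail mass
# (< 1e-15 per side) is far below the 1e-8 absolute tolerance used throughout.
.INT_SD_SPAN <- 8
.INT_ABS_TOL <- 1e-10

.integrate <- function(f, lower, upper, ...) {
  out <- tryCatch(
    stats::integrate(f, lower, upper, abs.tol = .INT_ABS_TOL,
                     rel.tol = .INT_ABS_TOL, stop.on.error = TRUE, ...),
    error = function(e) stop("numerical integration failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  out$value
}

# Evaluate a stochastic expression under an explicit seed, restoring the
# caller's RNG state afterwards so no global state leaks out.
.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.check_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  if (!.is_prob(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok)
    stop(sprintf("'%s' must be in %s%s, %s%s (got %g)", name,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]", x), call. = FALSE)
  invisible(x)
}

# weighted mean / variance (prevalence reweighting of case-control samples);
# weights are normalized to sum to length(x) and the variance uses the
# usual n-1 denominator on the normalized weights.
.wtd_mean <- function(x, w) sum(w * x) / sum(w)

.wtd_var <- function(x, w) {
  w <- w * length(x) / sum(w)
  m <- sum(w * x) / length(x)
  sum(w * (x - m)^2) / (length(x) - 1)
}
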