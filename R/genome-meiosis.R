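# Virtual couples and Mendelian embryo simulation with map-based
# Poisson recombination.

#' Form virtual couples matching the population status composition
#'
#' Randomly pairs cohort members (regardless of sex) so that the couple
#' status composition matches random mating at prevalence `K`: a fraction
#' \eqn{(1-K)^2} of couples are control-control, \eqn{K^2} case-case, and
#' \eqn{2K(1-K)} mixed (multinomial rounding).  The two members of a
#' couple are always distinct, and couples are unique as unordered pairs;
#' individuals are reused across couples, with a warning, when the cohort
#' is too small to avoid it.
#'
#' @param cohort A [phased_cohort()].
#' @param n_couples Number of couples to form.
#' @param K Population prevalence driving the composition.
#' @param seed Integer seed.
#' @return A data frame with columns `parent1`, `parent2` (sample
#'   indices), `status1`, `status2`.
#' @export
mate_virtual_couples <- function(cohort, n_couples, K, seed) {
  stopifnot(inherits(cohort, "phased_cohort"), n_couples >= 1)
  .check_fraction(K, "K")
  cases <- which(cohort$samples$status == "case")
  ctrls <- which(cohort$samples$status == "control")

  # multinomial rounding of the target composition
  f <- c(cc = (1 - K)^2, mixed = 2 * K * (1 - K), aa = K^2)
  cnt <- floor(f * n_couples)
  rem <- n_couples - sum(cnt)
  if (rem > 0) {
    extra <- order(f * n_couples - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }

  if (cnt["aa"] > 0 && length(cases) < 2)
    stop(sprintf("insufficient cases: %d case-case couples require >= 2 cases (have %d)",
                 cnt["aa"], length(cases)), call. = FALSE)
  if (cnt["mixed"] > 0 && (length(cases) < 1 || length(ctrls) < 1))
    stop(sprintf("insufficient samples for %d mixed couples (cases: %d, controls: %d)",
                 cnt["mixed"], length(cases), length(ctrls)), call. = FALSE)
  if (cnt["cc"] > 0 && length(ctrls) < 2)
    stop(sprintf("insufficient controls: %d control-control couples require >= 2 controls (have %d)",
                 cnt["cc"], length(ctrls)), call. = FALSE)
  if (2 * cnt["cc"] > length(ctrls) || 2 * cnt["aa"] > length(cases) ||
      cnt["mixed"] > min(length(cases), length(ctrls)))
    warning("cohort smaller than the requested couple set; individuals are reused across couples")

  .with_seed(seed, {
    draw_pairs <- function(pool1, pool2, m, same_pool) {
      if (m == 0) return(NULL)
      seen <- character(0)
      out <- matrix(0L, m, 2)
      for (i in seq_len(m)) {
        for (attempt in 1:10000) {
          a <- pool1[sample.int(length(pool1), 1)]
          b <- pool2[sample.int(length(pool2), 1)]
          if (a == b) next
          key <- paste(min(a, b), max(a, b))
          if (!(key %in% seen)) { seen <- c(seen, key); out[i, ] <- c(a, b); break }
          if (attempt == 10000)
            stop("could not form enough unique couples from this cohort",
                 call. = FALSE)
        }
      }
      out
    }
    pairs <- rbind(draw_pairs(ctrls, ctrls, cnt[["cc"]], TRUE),
                   draw_pairs(cases, ctrls, cnt[["mixed"]], FALSE),
                   draw_pairs(cases, cases, cnt[["aa"]], TRUE))
    data.frame(parent1 = pairs[, 1], parent2 = pairs[, 2],
               status1 = cohort$samples$status[pairs[, 1]],
               status2 = cohort$samples$status[pairs[, 2]],
               stringsAsFactors = FALSE)
  })
}

# precompute, per chromosome, the variant indices and their interpolated
# genetic positions; reused across all gametes drawn from a variant set
.map_index <- function(variants, map) {
  lapply(split(seq_len(nrow(variants)), variants$chrom), function(vi) {
    chr <- variants$chrom[vi[1]]
    mi <- map[map$chrom == chr, , drop = FALSE]
    if (nrow(mi) < 2)
      stop(sprintf("genetic map has no interval for chromosome %s", chr),
           call. = FALSE)
    mi <- mi[order(mi$bp), ]
    pos <- variants$pos[vi]
    if (any(pos < min(mi$bp) | pos > max(mi$bp)))
      stop(sprintf("variant outside genetic map range on chromosome %s", chr),
           call. = FALSE)
    list(vi = vi,
         v_cM = stats::approx(mi$bp, mi$cM, xout = pos, ties = "ordered")$y,
         cM_lo = min(mi$cM), cM_hi = max(mi$cM),
         L = (max(mi$cM) - min(mi$cM)) / 100)    # Morgan
  })
}

# one recombinant gamete from a phased parent genome.
# Crossover counts per chromosome are Poisson with mean the chromosome's
# map length in Morgan; positions are uniform in genetic distance.  A
# crossover falling exactly on a variant's cM position leaves that variant
# on the preceding (left) segment.
.gamete <- function(h1, h2, idx) {
  out <- integer(length(h1))
  for (ch in idx) {
    ncx <- if (ch$L > 0) stats::rpois(1L, ch$L) else 0L
    start <- sample.int(2L, 1L)              # transmitted strand at chr start
    if (ncx > 0) {
      cx <- sort.int(stats::runif(ncx, ch$cM_lo, ch$cM_hi))
      nswitch <- findInterval(ch$v_cM, cx, left.open = TRUE)  # # crossovers < v
    } else nswitch <- 0L
    use1 <- (start + nswitch) %% 2L == 1L    # TRUE -> strand h1
    vi <- ch$vi
    out[vi] <- h2[vi]
    out[vi[use1]] <- h1[vi[use1]]
  }
  out
}

#' Simulate embryo genomes from two phased parents
#'
#' Each embryo is the union of one recombinant gamete per parent.
#' Crossovers follow a Poisson process along the genetic map: the count
#' per chromosome is Poisson with mean equal to the chromosome map length
#' in Morgan, and positions are uniform in genetic distance, interpolated
#' to physical coordinates.  The transmitted strand at the start of each
#' chromosome is chosen at random.
#'
#' @param parent1,parent2 Phased genomes as returned by [get_genome()]
#'   (lists with `h1`, `h2`, `variants`); both parents must share the
#'   variant set.
#' @param map Genetic map covering all variant positions (no
#'   extrapolation).
#' @param n_embryos Number of embryos to simulate.
#' @param seed Integer seed.
#' @return An object of class `"pes_embryos"`: list with matrices `h1`
#'   (gametes from parent 1) and `h2` (from parent 2), each
#'   `n_embryos x n_variants`, plus the `variants` table.
#' @export
simulate_offspring <- function(parent1, parent2, map, n_embryos, seed) {
  stopifnot(is.list(parent1), is.list(parent2), n_embryos >= 1)
  if (!identical(parent1$variants$id, parent2$variants$id))
    stop("parents must share the same variant set", call. = FALSE)
  .with_seed(seed, .simulate_offspring_impl(parent1, parent2, map, n_embryos))
}

# RNG-stream-internal version used inside larger seeded pipelines;
# `idx` is an optional precomputed .map_index() for the shared variant set
.simulate_offspring_impl <- function(parent1, parent2, map, n_embryos,
                                     idx = NULL) {
  v <- parent1$variants
  if (is.null(idx)) idx <- .map_index(v, map)
  m <- nrow(v)
  g1 <- matrix(0L, n_embryos, m)
  g2 <- matrix(0L, n_embryos, m)
  for (e in seq_len(n_embryos)) {
    g1[e, ] <- .gamete(parent1$h1, parent1$h2, idx)
    g2[e, ] <- .gamete(parent2$h1, parent2$h2, idx)
  }
  structure(list(h1 = g1, h2 = g2, variants = v), class = "pes_embryos")
}

#' @export
print.pes_embryos <- function(x, ...) {
  cat(sprintf("Simulated embryos: %d embryos x %d variants\n",
              nrow(x$h1), ncol(x$h1)))
  invisible(x)
}
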