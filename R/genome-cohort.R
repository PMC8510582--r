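# Synthetic phased cohorts, genetic maps, additive score models, and the
# plain-text interchange formats (VCF with phased GT, tab-delimited map,
# PLINK-style score file).

#' Construct a phased cohort
#'
#' @param samples Data frame with columns `id` and `status`
#'   (`"case"`/`"control"`).
#' @param variants Data frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt`; positions must be strictly increasing within each
#'   chromosome.
#' @param h1,h2 Integer 0/1 matrices (samples x variants): the two phased
#'   haplotypes of every sample.
#' @return An object of class `"phased_cohort"`.
#' @export
phased_cohort <- function(samples, variants, h1, h2) {
  stopifnot(is.data.frame(samples), all(c("id", "status") %in% names(samples)),
            is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)),
            is.matrix(h1), is.matrix(h2),
            all(dim(h1) == dim(h2)),
            nrow(h1) == nrow(samples), ncol(h1) == nrow(variants))
  if (!all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L)))
    stop("haplotypes must be coded 0/1", call. = FALSE)
  if (any(tapply(variants$pos, variants$chrom, function(p) any(diff(p) <= 0)),
          na.rm = TRUE))
    stop("variant positions must be strictly increasing within chromosome",
         call. = FALSE)
  if (!all(samples$status %in% c("case", "control")))
    stop("sample status must be 'case' or 'control'", call. = FALSE)
  structure(list(samples = samples, variants = variants,
                 h1 = h1, h2 = h2),
            class = "phased_cohort")
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat(sprintf("Phased cohort: %d samples (%d cases, %d controls), %d variants on %d chromosome(s)\n",
              nrow(x$samples), sum(x$samples$status == "case"),
              sum(x$samples$status == "control"), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

# diploid allele-dosage matrix (samples x variants)
.dosages <- function(cohort) cohort$h1 + cohort$h2

#' Generate a synthetic case-control cohort under the liability model
#'
#' Simulates a population of unrelated, phased genomes with independent
#' variants in Hardy-Weinberg equilibrium, an additive genetic score with
#' normal per-variant weights scaled so the score explains
#' `target_r2_liab` of the liability variance, and a normal residual.
#' Individuals with liability above the prevalence threshold are cases;
#' simulation continues until the requested numbers of cases and controls
#' are collected.  A piecewise-linear genetic map with constant `cm_per_mb`
#' is emitted alongside the cohort and score model.
#'
#' @param n_cases,n_controls Samples of each status to collect.
#' @param n_variants Number of score variants.
#' @param n_chromosomes Chromosomes over which variants are spread in
#'   contiguous blocks.
#' @param maf_range Minor-allele-frequency interval, within (0, 0.5].
#' @param target_r2_liab Liability-scale variance the score should explain.
#' @param K Prevalence used for the liability threshold.
#' @param seed Integer seed.
#' @param bp_spacing Physical spacing between adjacent variants (bp).  The
#'   default 1 Mb, with the default map rate, gives chromosomes on the
#'   order of a Morgan, so score loci segregate near-independently as they
#'   do for a genome-wide score.
#' @param cm_per_mb Map rate (centimorgan per megabase).
#' @return A list with elements `cohort` ([phased_cohort()]), `map`
#'   (genetic map data frame), and `score` (score model data frame).
#' @examples
#' syn <- generate_synthetic_cohort(30, 30, n_variants = 50,
#'                                  n_chromosomes = 2,
#'                                  target_r2_liab = 0.1, K = 0.2, seed = 1)
#' syn$cohort
#' @export
generate_synthetic_cohort <- function(n_cases, n_controls, n_variants,
                                      n_chromosomes = 2,
                                      maf_range = c(0.1, 0.5),
                                      target_r2_liab, K, seed,
                                      bp_spacing = 1e6, cm_per_mb = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_variants >= 1, n_chromosomes >= 1)
  .check_fraction(K, "K", lo_open = TRUE, hi_open = TRUE)
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  .check_fraction(target_r2_liab, "target_r2_liab", lo_open = TRUE, hi_open = TRUE)
  if (target_r2_liab >= 0.95)
    stop("target_r2_liab too close to 1 to be attainable with a finite score",
         call. = FALSE)

  .with_seed(seed, {
    maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
    w <- stats::rnorm(n_variants)
    vG <- sum(w^2 * 2 * maf * (1 - maf))
    if (vG <= 0)
      stop("infeasible target r2: zero genetic variance from the drawn weights",
         call. = FALSE)
    w <- w * sqrt(target_r2_liab / vG)   # Var(score) = target r2 on liability
    mu_G <- sum(w * 2 * maf)             # population mean of the raw score
    zK <- liability_threshold(K)
    s_res <- sqrt(1 - target_r2_liab)

    keep_h1 <- list(); keep_h2 <- list(); keep_status <- character(0)
    got_case <- 0; got_ctrl <- 0
    while (got_case < n_cases || got_ctrl < n_controls) {
      M <- 2000L
      H1 <- matrix(stats::rbinom(M * n_variants, 1L, rep(maf, each = M)),
                   M, n_variants)
      H2 <- matrix(stats::rbinom(M * n_variants, 1L, rep(maf, each = M)),
                   M, n_variants)
      G <- as.vector((H1 + H2) %*% w) - mu_G
      liab <- G + stats::rnorm(M, sd = s_res)
      is_case <- liab > zK
      take_case <- which(is_case)[seq_len(min(sum(is_case), n_cases - got_case))]
      take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case), n_controls - got_ctrl))]
      idx <- c(take_case, take_ctrl)
      if (length(idx)) {
        keep_h1[[length(keep_h1) + 1L]] <- H1[idx, , drop = FALSE]
        keep_h2[[length(keep_h2) + 1L]] <- H2[idx, , drop = FALSE]
        keep_status <- c(keep_status,
                         rep(c("case", "control"),
                             c(length(take_case), length(take_ctrl))))
      }
      got_case <- got_case + length(take_case)
      got_ctrl <- got_ctrl + length(take_ctrl)
    }
    h1 <- do.call(rbind, keep_h1)
    h2 <- do.call(rbind, keep_h2)
    ord <- order(keep_status == "control")  # cases first, stable
    h1 <- h1[ord, , drop = FALSE]; h2 <- h2[ord, , drop = FALSE]
    status <- keep_status[ord]

    chrom <- rep(seq_len(n_chromosomes), each = ceiling(n_variants / n_chromosomes),
                 length.out = n_variants)
    pos <- unlist(lapply(split(seq_len(n_variants), chrom),
                         function(i) seq_along(i) * bp_spacing), use.names = FALSE)
    variants <- data.frame(chrom = chrom, pos = pos,
                           id = sprintf("rs%06d", seq_len(n_variants)),
                           ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
    samples <- data.frame(id = sprintf("S%04d", seq_along(status)),
                          status = status, stringsAsFactors = FALSE)
    cohort <- phased_cohort(samples, variants, h1, h2)

    # map: anchor rows at 0 and just beyond the last variant per chromosome
    map <- do.call(rbind, lapply(split(variants, variants$chrom), function(v) {
      span <- max(v$pos) + bp_spacing
      data.frame(chrom = v$chrom[1], bp = c(0, span),
                 cM = c(0, span / 1e6 * cm_per_mb))
    }))
    rownames(map) <- NULL
    class(map) <- c("genetic_map", "data.frame")

    score <- data.frame(id = variants$id, effect_allele = "G", weight = w,
                        stringsAsFactors = FALSE)
    class(score) <- c("score_model", "data.frame")

    list(cohort = cohort, map = map, score = score)
  })
}

#' Extract one sample's phased genome
#'
#' @param cohort A [phased_cohort()].
#' @param i Sample index or id.
#' @return A list with elements `h1`, `h2` (0/1 vectors) and `variants`.
#' @export
get_genome <- function(cohort, i) {
  stopifnot(inherits(cohort, "phased_cohort"))
  if (is.character(i)) i <- match(i, cohort$samples$id)
  stopifnot(!is.na(i), i >= 1, i <= nrow(cohort$samples))
  list(h1 = cohort$h1[i, ], h2 = cohort$h2[i, ], variants = cohort$variants)
}

# ---- plain-text IO -------------------------------------------------------

#' Read and write cohort interchange files
#'
#' `write_cohort_vcf()` emits an uncompressed VCF 4.2 with phased `GT`
#' fields; `read_phased_cohort()` reads one back (any VCF with fully
#' phased, biallelic GT records), attaching case/control statuses supplied
#' separately.  `read_genetic_map()`/`write_genetic_map()` use a
#' tab-delimited table with header columns `chrom`, `bp`, `cM`;
#' `read_score_model()`/`write_score_model()` use a whitespace-delimited
#' PLINK-score-style file with columns variant id, effect allele, weight.
#'
#' @param cohort A [phased_cohort()].
#' @param path File path.
#' @param statuses Character vector of `"case"`/`"control"`, either named
#'   by sample id or in VCF sample order.
#' @return The written path (writers, invisibly) or the parsed object
#'   (readers).
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "phased_cohort"))
  v <- cohort$variants
  gt <- matrix(paste0(t(cohort$h1), "|", t(cohort$h2)),
               nrow = nrow(v))                  # variants x samples
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=pesrisk-synthetic-cohort",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$id), collapse = "\t"),
    paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_phased_cohort <- function(path, statuses) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes found ('/' separator); phased GT required",
         call. = FALSE)
  if (!all(gt %in% c("0|0", "0|1", "1|0", "1|1")))
    stop("only biallelic phased 0/1 genotypes are supported", call. = FALSE)
  ids <- colnames(gt)
  if (!is.null(names(statuses))) statuses <- statuses[ids]
  if (length(statuses) != length(ids) || anyNA(statuses))
    stop("a status is required for every sample", call. = FALSE)
  h1 <- t(matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt)))
  h2 <- t(matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt)))
  variants <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"], ref = fix[, "REF"],
                         alt = fix[, "ALT"], stringsAsFactors = FALSE)
  phased_cohort(data.frame(id = ids, status = unname(statuses),
                           stringsAsFactors = FALSE),
                variants, h1, h2)
}

#' @rdname cohort_io
#' @param map A genetic map data frame (`chrom`, `bp`, `cM`).
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(all(c("chrom", "bp", "cM") %in% names(map)))
  utils::write.table(as.data.frame(map)[, c("chrom", "bp", "cM")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "bp", "cM") %in% names(map)))
  bad <- tapply(seq_len(nrow(map)), map$chrom, function(i) {
    o <- order(map$bp[i]); any(diff(map$cM[i][o]) < 0)
  })
  if (any(unlist(bad)))
    stop("cM must be non-decreasing in bp within each chromosome",
         call. = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @rdname cohort_io
#' @param score A score model data frame (`id`, `effect_allele`, `weight`).
#' @export
write_score_model <- function(score, path) {
  stopifnot(all(c("id", "effect_allele", "weight") %in% names(score)))
  utils::write.table(as.data.frame(score)[, c("id", "effect_allele", "weight")],
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_score_model <- function(path) {
  sc <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "effect_allele", "weight"))
  sc$weight <- as.numeric(sc$weight)
  class(sc) <- c("score_model", "data.frame")
  sc
}
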