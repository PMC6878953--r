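#' Pool-Seq binomial coverage sampling
#'
#' Emulates sequencing a population as a pool: the observed
#' derived-allele count at each locus is `Binomial(coverage, frequency)`,
#' independently per locus and per sample. `coverage = Inf` (the exact
#' sentinel) returns the true counts unchanged.
#'
#' @param frequencies per-locus allele frequencies in `[0, 1]`.
#' @param coverage read depth (>= 1), or `Inf` for exact counts.
#' @param true_counts,true_depth the exact counts/depth returned in
#'   exact mode (`true_counts` defaults to `frequencies * true_depth`).
#' @return list with `counts` and `depth` (scalar) of the sampled
#'   alleles.
#' @export
poolseq_sample <- function(frequencies, coverage, true_counts = NULL,
                           true_depth = NULL) {
  if (any(frequencies < 0 | frequencies > 1))
    stop("frequencies must lie in [0, 1]")
  if (is.infinite(coverage)) {
    if (is.null(true_depth)) stop("exact mode needs true_depth")
    if (is.null(true_counts)) true_counts <- round(frequencies * true_depth)
    return(list(counts = as.integer(true_counts),
                depth = as.integer(true_depth)))
  }
  if (coverage < 1) stop("coverage must be >= 1")
  list(counts = rbinom(length(frequencies), coverage, frequencies),
       depth = as.integer(coverage))
}

# Vectorized Mantel-Haenszel chi-square without continuity correction.
# Inputs are loci x k matrices of the four 2x2 cells per stratum:
#   A = base major, B = base minor, C = evolved major, D = evolved minor.
# Strata with a zero margin contribute 0 to numerator and denominator;
# loci with zero total variance get statistic 0 and p = 1.
cmh_core <- function(A, B, C, D) {
  r1 <- A + B; r2 <- C + D
  c1 <- A + C; c2 <- B + D
  n <- r1 + r2
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0 & n > 1
  E <- ifelse(ok, r1 * c1 / n, 0)
  V <- ifelse(ok, r1 * r2 * c1 * c2 / (n^2 * (n - 1)), 0)
  num <- rowSums(ifelse(ok, A, 0) - E)
  den <- rowSums(V)
  stat <- ifelse(den > 0, num^2 / den, 0)
  p <- ifelse(den > 0, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(statistic = stat, p.value = p)
}

#' Cochran-Mantel-Haenszel test for one locus
#'
#' Meta-analysis of a 2 x 2 x k contingency table: per replicate
#' (stratum) the rows are (base, evolved) and the columns the counts of
#' the two alleles. The statistic is the Mantel-Haenszel chi-square with
#' 1 df and *no* continuity correction,
#' `T = (sum_r (a_r - E_r))^2 / sum_r V_r` with
#' `E_r = row1_r col1_r / n_r` and
#' `V_r = row1_r row2_r col1_r col2_r / (n_r^2 (n_r - 1))`.
#' The null hypothesis is the absence of differentiation between the
#' base and the evolved populations. Strata with a zero margin
#' contribute nothing; a locus with zero total variance (e.g. fixed
#' identically everywhere) returns `p = 1`. The statistic is invariant
#' to swapping the column labels in all strata simultaneously.
#'
#' @param tables a `2 x 2 x k` array (or a single 2 x 2 matrix, or a
#'   list of 2 x 2 matrices), rows = (base, evolved), columns =
#'   (major, minor).
#' @return list with `statistic` and `p.value`.
#' @export
cmh_test <- function(tables) {
  if (is.list(tables)) tables <- simplify2array(tables)
  if (is.matrix(tables)) tables <- array(tables, c(2, 2, 1))
  if (length(dim(tables)) != 3 || any(dim(tables)[1:2] != 2))
    stop("tables must be a 2 x 2 x k array")
  k <- dim(tables)[3]
  if (k < 1) stop("empty stratum set")
  if (any(apply(tables, 3, sum) <= 0))
    stop("every stratum must have a positive total")
  A <- matrix(tables[1, 1, ], 1); B <- matrix(tables[1, 2, ], 1)
  C <- matrix(tables[2, 1, ], 1); D <- matrix(tables[2, 2, ], 1)
  res <- cmh_core(A, B, C, D)
  list(statistic = unname(res$statistic), p.value = unname(res$p.value))
}

#' Score an experiment with the CMH test
#'
#' Builds, per locus and replicate, the 2 x 2 table contrasting the
#' (shared) base population at generation 0 against the evolved
#' replicate at the final recorded generation, polarized to the base
#' population's major allele (an exact 50% tie counts the ancestral
#' allele as major). Optional Pool-Seq binomial sampling is applied to
#' the evolved samples and (by default) also to the base sample. The
#' per-replicate frequency changes are polarized to the base *minor*
#' allele.
#'
#' @param store a `trajectory_store`.
#' @param coverage Pool-Seq read depth, or `Inf` (default) for exact
#'   counts.
#' @param sample_base also Pool-Seq sample the base population (default
#'   `TRUE`; ignored in exact mode).
#' @return data.frame with one row per locus: `chrom`, `pos`,
#'   `p_value`, `score` (`-log10 p`), `is_qtn`, `effect`, `base_freq`,
#'   plus the per-replicate frequency-change matrix as attribute
#'   `"dfreq"`.
#' @export
score_experiment <- function(store, coverage = Inf, sample_base = TRUE) {
  n_t <- length(store$gens)
  d0 <- store$counts[, 1, 1]                    # shared founded base
  dT <- store$counts[, n_t, , drop = TRUE]
  dT <- matrix(dT, nrow = dim(store$counts)[1], ncol = store$k)
  depth0 <- 2L * store$N
  f0 <- d0 / depth0
  major_is_derived <- f0 > 0.5                  # tie -> ancestral major

  k <- store$k
  if (is.finite(coverage)) {
    if (sample_base) {
      bs <- poolseq_sample(f0, coverage)
      b_der <- bs$counts; b_depth <- bs$depth
    } else {
      b_der <- d0; b_depth <- depth0
    }
    e_der <- matrix(0L, length(d0), k)
    for (r in seq_len(k))
      e_der[, r] <- poolseq_sample(dT[, r] / depth0, coverage)$counts
    e_depth <- as.integer(coverage)
  } else {
    b_der <- d0; b_depth <- depth0
    e_der <- dT; e_depth <- depth0
  }

  # polarize to base major allele
  A <- ifelse(major_is_derived, b_der, b_depth - b_der)   # base major
  B <- b_depth - A
  Am <- matrix(A, length(A), k); Bm <- matrix(B, length(B), k)
  Cm <- ifelse(matrix(major_is_derived, length(A), k), e_der,
               e_depth - e_der)
  Dm <- e_depth - Cm
  res <- cmh_core(Am, Bm, Cm, Dm)

  # frequency change of the base minor allele
  minor_f0 <- ifelse(major_is_derived, 1 - f0, f0)
  minor_fT <- ifelse(matrix(major_is_derived, length(A), k),
                     1 - dT / depth0, dT / depth0)
  dfreq <- minor_fT - minor_f0

  is_qtn <- logical(length(d0)); is_qtn[store$arch$qtn_idx] <- TRUE
  effect <- rep(NA_real_, length(d0))
  effect[store$arch$qtn_idx] <- store$arch$effects
  out <- data.frame(chrom = store$loci$chrom, pos = store$loci$pos,
                    p_value = res$p.value,
                    score = -log10(pmax(res$p.value, .Machine$double.xmin)),
                    is_qtn = is_qtn, effect = effect, base_freq = f0,
                    stringsAsFactors = FALSE)
  attr(out, "dfreq") <- dfreq
  out
}

#' Write / read allele counts in PoPoolation2 sync format
#'
#' Columns: chromosome, position, reference base (always `N`), then one
#' `A:T:C:G:N:del` field per sample, with the ancestral allele mapped to
#' `A` and the derived allele to `T`.
#'
#' @param loci data.frame with `chrom`, `pos`.
#' @param samples list of two-column matrices (ancestral count, derived
#'   count), one per sample, each with one row per locus.
#' @param path file path.
#' @return `write_sync` returns `path` invisibly; `read_sync` returns
#'   `list(loci, samples)` with counts recovered exactly.
#' @export
write_sync <- function(loci, samples, path) {
  if (nrow(loci) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  fields <- lapply(samples, function(m)
    sprintf("%d:%d:0:0:0:0", as.integer(m[, 1]), as.integer(m[, 2])))
  lines <- do.call(paste, c(list(loci$chrom, loci$pos, "N"), fields,
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sync
#' @export
read_sync <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(list(loci = data.frame(chrom = character(0), pos = integer(0)),
                samples = list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != nf[1])) stop("ragged sync file")
  n_samp <- nf[1] - 3
  loci <- data.frame(chrom = vapply(parts, `[`, "", 1),
                     pos = as.integer(vapply(parts, `[`, "", 2)),
                     stringsAsFactors = FALSE)
  samples <- vector("list", n_samp)
  for (s in seq_len(n_samp)) {
    cnt <- t(vapply(parts, function(p) {
      as.integer(strsplit(p[3 + s], ":", fixed = TRUE)[[1]])
    }, integer(6)))
    samples[[s]] <- cnt[, 1:2, drop = FALSE]
  }
  list(loci = loci, samples = samples)
}

#' Export a trajectory store as a sync time series
#'
#' One sample column per replicate and recorded generation, ordered
#' base (generation 0) first and then replicate-major
#' (`rep1@g1, rep1@g2, ..., rep2@g1, ...`), so external time-series
#' test statistics can be applied.
#'
#' @param store a `trajectory_store`.
#' @param path file path.
#' @export
write_sync_from_store <- function(store, path) {
  depth <- 2L * store$N
  samples <- list(cbind(depth - store$counts[, 1, 1],
                        store$counts[, 1, 1]))
  later <- which(store$gens > 0)
  for (r in seq_len(store$k))
    for (ti in later)
      samples[[length(samples) + 1]] <-
        cbind(depth - store$counts[, ti, r], store$counts[, ti, r])
  write_sync(store$loci, samples, path)
}
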