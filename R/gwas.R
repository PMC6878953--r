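#' Build nested GWAS cohorts from a founder pool
#'
#' The largest cohort samples `2 * size` haplotypes from the pool with
#' replacement and pairs them into diploids; each smaller cohort samples
#' its haplotypes *without replacement* from the next larger cohort's
#' haplotype multiset, so SNPs segregating in a smaller cohort are a
#' subset of those segregating in every larger one. A trait architecture
#' is drawn on the pool and redrawn (up to `max_retries` times) until
#' every QTN's frequency lies within `freq_bounds` in *every* cohort.
#' Phenotypes use the same additive model and heritability calibration
#' as the E&R simulations, with the genotypic variance computed in the
#' largest cohort.
#'
#' @param pool a `haplotype_pool`.
#' @param sizes cohort sizes (diploid individuals); sorted descending
#'   internally.
#' @param n_qtn,effect_distribution,freq_bounds,h2 trait-architecture
#'   parameters as in [draw_architecture()].
#' @param seed integer seed.
#' @param max_retries architecture redraw budget (default 100).
#' @return An object of class `cohort_set`: list with `sizes`
#'   (descending), `hap_idx` (list of haplotype index vectors into the
#'   pool; individual `i` owns entries `2i-1`, `2i`), `arch`, `Ve`,
#'   `phenotypes` (list, one vector per cohort) and `pool`.
#' @export
build_cohorts <- function(pool, sizes, n_qtn = 100,
                          effect_distribution = effect_gamma(0.42, 1),
                          freq_bounds = c(0.05, 0.95), h2 = 1, seed = 1,
                          max_retries = 100) {
  sizes <- sort(as.integer(sizes), decreasing = TRUE)
  n_hap_pool <- nrow(pool$alleles)
  with_seed(seed, {
    hap_idx <- vector("list", length(sizes))
    hap_idx[[1]] <- sample.int(n_hap_pool, 2 * sizes[1], replace = TRUE)
    for (i in seq_along(sizes)[-1]) {
      if (2 * sizes[i] > length(hap_idx[[i - 1]]))
        stop("cohort sizes must be non-increasing")
      hap_idx[[i]] <- sample(hap_idx[[i - 1]], 2 * sizes[i],
                             replace = FALSE)
    }
    arch <- NULL
    for (try in seq_len(max_retries)) {
      cand <- draw_architecture(pool, n_qtn, effect_distribution,
                                freq_bounds, h2)
      ok <- TRUE
      for (i in seq_along(sizes)) {
        f <- colMeans(pool$alleles[hap_idx[[i]], cand$qtn_idx,
                                   drop = FALSE])
        if (any(f < freq_bounds[1] | f > freq_bounds[2])) {
          ok <- FALSE
          break
        }
      }
      if (ok) { arch <- cand; break }
    }
    if (is.null(arch))
      stop("no architecture satisfied the frequency bounds in all ",
           "cohorts after ", max_retries, " redraws")
    # heritability calibrated on the largest cohort's realized variance
    dos1 <- cohort_dosage_matrix(pool, hap_idx[[1]], arch$qtn_idx)
    G1 <- drop(dos1 %*% arch$effects)
    Ve <- calibrate_env_variance(var(G1), h2)
    phenos <- vector("list", length(sizes))
    phenos[[1]] <- phenotype_individuals(G1, Ve)
    for (i in seq_along(sizes)[-1]) {
      dos <- cohort_dosage_matrix(pool, hap_idx[[i]], arch$qtn_idx)
      phenos[[i]] <- phenotype_individuals(drop(dos %*% arch$effects), Ve)
    }
    structure(list(sizes = sizes, hap_idx = hap_idx, arch = arch,
                   Ve = Ve, phenotypes = phenos, pool = pool),
              class = "cohort_set")
  })
}

# dosage matrix (individuals x selected loci) for a haplotype index set
cohort_dosage_matrix <- function(pool, hidx, loci_idx = NULL) {
  al <- if (is.null(loci_idx)) pool$alleles[hidx, , drop = FALSE]
        else pool$alleles[hidx, loci_idx, drop = FALSE]
  n2 <- nrow(al)
  al[seq(1, n2, by = 2), , drop = FALSE] +
    al[seq(2, n2, by = 2), , drop = FALSE]
}

#' Genotype dosages of one cohort
#' @param cohorts a `cohort_set`.
#' @param i cohort index (1 = largest).
#' @return integer matrix (individuals x pool loci) of derived-allele
#'   dosages.
#' @export
cohort_dosages <- function(cohorts, i) {
  cohort_dosage_matrix(cohorts$pool, cohorts$hap_idx[[i]])
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("<cohort_set> sizes: ", paste(x$sizes, collapse = ", "),
      "; ", length(x$arch$qtn_idx), " QTNs, h2 = ", x$arch$h2, "\n",
      sep = "")
  invisible(x)
}

#' Single-marker additive association scan
#'
#' Per locus, an ordinary least-squares regression of the raw phenotype
#' on the derived-allele dosage with an intercept; the p-value is the
#' two-sided test of zero slope (t distribution, `n - 2` df). For hard
#' genotypes this is the additive linear-model test that
#' expected-dosage frequentist GWAS software reduces to. Monomorphic
#' loci are flagged non-testable and given `p = 1`.
#'
#' @param dosages numeric/integer matrix (individuals x loci), values in
#'   `{0, 1, 2}`.
#' @param phenotypes numeric vector of length `nrow(dosages)`.
#' @return data.frame with one row per locus: `beta`, `se`, `t`, `p`,
#'   `testable`.
#' @export
association_scan <- function(dosages, phenotypes) {
  n <- length(phenotypes)
  if (nrow(dosages) != n) stop("dimension mismatch")
  if (n < 3) stop("need at least 3 individuals")
  if (any(!is.finite(phenotypes))) stop("phenotypes must be finite")
  y <- phenotypes - mean(phenotypes)
  Syy <- sum(y^2)
  sx <- colSums(dosages)
  Sxx <- colSums(dosages^2) - sx^2 / n
  Sxy <- drop(crossprod(dosages, y))
  testable <- Sxx > 0
  beta <- ifelse(testable, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - ifelse(testable, beta * Sxy, 0), 0)
  se <- ifelse(testable, sqrt(rss / (n - 2) / Sxx), NA_real_)
  tstat <- ifelse(testable & se > 0, beta / se,
                  ifelse(testable, Inf * sign(beta), NA_real_))
  p <- ifelse(testable, 2 * pt(-abs(tstat), df = n - 2), 1)
  data.frame(beta = beta, se = se, t = tstat, p = p, testable = testable)
}

#' Compare detection power between methods
#'
#' For each named score vector (e.g. GWAS scans at several cohort sizes
#' and an E&R scan), computes the ROC/pAUC at `f_max` and, to address
#' differing SNP counts between cohorts, the true-positive rate at a
#' fixed number of false positives (`fp_count`; at 0 this is the
#' fraction of causative loci scoring above the best neutral locus).
#'
#' @param scores_list named list of score vectors (larger = more
#'   significant; use `-log10(p)`).
#' @param labels_list list of logical label vectors matching
#'   `scores_list`, or a single vector shared by all methods.
#' @param f_max pAUC cutoff (default 0.01).
#' @param fp_count false-positive budget for the fixed-FP variant
#'   (default 0).
#' @return list with `summary` (data.frame: method, pauc,
#'   tpr_at_fp) and `rocs` (named list of `roc_result`).
#' @export
compare_power <- function(scores_list, labels_list, f_max = 0.01,
                          fp_count = 0) {
  if (!is.list(labels_list)) {
    labels_list <- rep(list(labels_list), length(scores_list))
  }
  methods <- names(scores_list)
  rocs <- vector("list", length(scores_list))
  tpr_fp <- numeric(length(scores_list))
  pauc <- numeric(length(scores_list))
  for (i in seq_along(scores_list)) {
    s <- scores_list[[i]]; l <- as.logical(labels_list[[i]])
    rocs[[i]] <- roc_pauc(s, l, f_max)
    pauc[i] <- rocs[[i]]$pauc
    neg <- sort(s[!l], decreasing = TRUE)
    thr <- if (fp_count < length(neg)) neg[fp_count + 1] else -Inf
    tpr_fp[i] <- mean(s[l] > thr)
  }
  names(rocs) <- methods
  list(summary = data.frame(method = methods, pauc = pauc,
                            tpr_at_fp = tpr_fp,
                            stringsAsFactors = FALSE),
       rocs = rocs, fp_count = fp_count)
}
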