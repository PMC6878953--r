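#' ROC curve and partial AUC
#'
#' Builds the ROC curve by sweeping the score threshold over all
#' distinct score values (ties form a single threshold, giving diagonal
#' segments) and integrates the true-positive rate over the
#' false-positive-rate interval `[0, f_max]` by the trapezoid rule with
#' linear interpolation at `f_max`. A perfect ranking attains
#' `pAUC = f_max`; uninformative (all-tied) scores give the chance value
#' `f_max^2 / 2`.
#'
#' @param scores numeric vector, larger = more significant.
#' @param labels logical (or 0/1) vector, `TRUE` for causative loci.
#' @param f_max FPR cutoff of the partial AUC (default 0.01).
#' @return An object of class `roc_result`: list with `fpr`, `tpr`
#'   (curve vertices including (0,0) and (1,1)), `pauc`, `f_max`,
#'   `n_pos`, `n_neg`.
#' @export
roc_pauc <- function(scores, labels, f_max = 0.01) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present (", n_pos, " positives, ",
         n_neg, " negatives)")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  cut <- c(which(diff(s) != 0), length(s))   # last index of each tie group
  tpr <- c(0, cumsum(l)[cut] / n_pos)
  fpr <- c(0, cumsum(!l)[cut] / n_neg)
  structure(list(fpr = fpr, tpr = tpr,
                 pauc = pauc_trapezoid(fpr, tpr, f_max),
                 f_max = f_max, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

# trapezoid integral of the piecewise-linear ROC over [0, f_max],
# interpolating linearly at f_max
pauc_trapezoid <- function(fpr, tpr, f_max) {
  if (f_max <= 0) return(0)
  f_max <- min(f_max, max(fpr))
  keep <- fpr <= f_max
  fs <- fpr[keep]; ts <- tpr[keep]
  if (max(fs) < f_max) {
    j <- which(fpr > f_max)[1]
    t_at <- tpr[j - 1] + (tpr[j] - tpr[j - 1]) *
      (f_max - fpr[j - 1]) / (fpr[j] - fpr[j - 1])
    fs <- c(fs, f_max); ts <- c(ts, t_at)
  }
  sum(diff(fs) * (head(ts, -1) + tail(ts, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> pAUC = ", signif(x$pauc, 4), " over FPR [0, ",
      x$f_max, "] (", x$n_pos, " positives, ", x$n_neg, " negatives)\n",
      sep = "")
  invisible(x)
}

#' Average ROC curves across repetitions
#'
#' Vertical averaging: the TPR of each curve is linearly interpolated on
#' a common FPR grid and averaged. The partial AUC is reported both as
#' the mean of the per-repetition pAUCs (`mean_pauc`, used for regime
#' comparisons) and as the pAUC of the averaged curve (`pauc`).
#'
#' @param rocs list of `roc_result` objects with a common `f_max`.
#' @param grid optional FPR grid; defaults to a grid dense on
#'   `[0, f_max]` and coarser beyond.
#' @return An object of class `roc_result` with extra fields
#'   `mean_pauc` and `pauc_per_repetition`.
#' @export
average_roc <- function(rocs, grid = NULL) {
  f_max <- rocs[[1]]$f_max
  if (any(vapply(rocs, function(r) r$f_max, 0) != f_max))
    stop("all curves must share f_max")
  if (is.null(grid))
    grid <- sort(unique(c(seq(0, f_max, length.out = 201),
                          seq(0, 1, length.out = 201))))
  tprs <- vapply(rocs, function(r)
    approx(r$fpr, r$tpr, xout = grid, ties = max, rule = 2)$y,
    numeric(length(grid)))
  tpr <- rowMeans(tprs)
  paucs <- vapply(rocs, function(r) r$pauc, 0)
  structure(list(fpr = grid, tpr = tpr,
                 pauc = pauc_trapezoid(grid, tpr, f_max),
                 mean_pauc = mean(paucs), pauc_per_repetition = paucs,
                 f_max = f_max,
                 n_pos = rocs[[1]]$n_pos, n_neg = rocs[[1]]$n_neg),
            class = "roc_result")
}

#' Classify non-causative loci as hitchhikers, drift-like or inconsistent
#'
#' A non-QTN locus is a *hitchhiker* when its allele-frequency change
#' has the same (nonzero) sign in all `k` replicates; it is *drift-like*
#' when the majority-direction count lies in
#' `[ceiling(0.4 k), floor(0.6 k)]` (4-6 of 10 replicates at `k = 10`);
#' anything else is *inconsistent*. QTNs are excluded and labelled
#' `"qtn"`.
#'
#' @param dfreq numeric matrix (loci x replicates) of signed frequency
#'   changes (e.g. `attr(score_experiment(...), "dfreq")`).
#' @param is_qtn logical vector of causative-locus labels.
#' @return character vector with values `"hitchhiker"`, `"drift-like"`,
#'   `"inconsistent"` or `"qtn"`.
#' @export
classify_consistency <- function(dfreq, is_qtn) {
  k <- ncol(dfreq)
  n_pos <- rowSums(dfreq > 0)
  n_neg <- rowSums(dfreq < 0)
  n_zero <- k - n_pos - n_neg
  hh <- n_zero == 0 & (n_pos == k | n_neg == k)
  maj <- pmax(n_pos, n_neg)
  drift <- !hh & maj >= ceiling(0.4 * k) & maj <= floor(0.6 * k)
  out <- ifelse(hh, "hitchhiker",
                ifelse(drift, "drift-like", "inconsistent"))
  out[is_qtn] <- "qtn"
  out
}

#' Fixation timing of causative alleles
#'
#' Trajectories are polarized to the selected (beneficial) allele: the
#' derived allele when the effect is positive, the ancestral allele
#' otherwise. The fixation generation is the first *recorded* generation
#' at which the selected allele count reaches `2N` (resolution is
#' therefore `record_every`); QTNs unfixed by the final generation are
#' censored and excluded from class means. Classes split at
#' `|a| > strong_threshold` (strong) versus `|a| <= strong_threshold`
#' (weak).
#'
#' @param store a `trajectory_store`.
#' @param strong_threshold effect-size threshold (default 1).
#' @return list with `per_qtn` (data.frame: qtn, replicate, effect,
#'   class, fixation_gen with NA = censored) and `mean_fixation`
#'   (named vector, mean fixation generation among fixed strong / weak
#'   QTNs).
#' @export
fixation_stats <- function(store, strong_threshold = 1) {
  qtn <- store$arch$qtn_idx
  eff <- store$arch$effects
  twoN <- 2L * store$N
  gens <- store$gens
  rows <- vector("list", store$k)
  for (r in seq_len(store$k)) {
    tr <- store$counts[qtn, , r, drop = FALSE][, , 1]
    tr <- matrix(tr, nrow = length(qtn))
    sel <- ifelse(matrix(eff > 0, length(qtn), ncol(tr)), tr, twoN - tr)
    fix_ti <- apply(sel == twoN, 1, function(z)
      if (any(z)) which(z)[1] else NA_integer_)
    rows[[r]] <- data.frame(qtn = qtn, replicate = r, effect = eff,
                            class = ifelse(abs(eff) > strong_threshold,
                                           "strong", "weak"),
                            fixation_gen = gens[fix_ti])
  }
  per_qtn <- do.call(rbind, rows)
  fixed <- per_qtn[!is.na(per_qtn$fixation_gen), ]
  mean_fix <- c(
    strong = if (any(fixed$class == "strong"))
      mean(fixed$fixation_gen[fixed$class == "strong"]) else NA_real_,
    weak = if (any(fixed$class == "weak"))
      mean(fixed$fixation_gen[fixed$class == "weak"]) else NA_real_)
  list(per_qtn = per_qtn, mean_fixation = mean_fix,
       prop_fixed = mean(!is.na(per_qtn$fixation_gen)))
}

#' Phenotypic response to selection
#'
#' `R_r` is the difference between the mean phenotype of replicate `r`
#' at the final generation and at generation 0; `R` averages over
#' replicates.
#'
#' @param store a `trajectory_store`.
#' @return list with `R` (mean response, trait units) and
#'   `per_replicate`.
#' @export
selection_response <- function(store) {
  ph <- store$pheno
  gmax <- max(ph$generation)
  per <- vapply(seq_len(store$k), function(r) {
    ph$mean_P[ph$replicate == r & ph$generation == gmax] -
      ph$mean_P[ph$replicate == r & ph$generation == 0]
  }, 0)
  list(R = mean(per), per_replicate = per)
}

#' QTN recovery among the top-ranked loci
#'
#' Fraction of causative loci found within the `top_k` highest-scoring
#' loci, overall and stratified by effect class
#' (`|a| >`/`<= effect_threshold`) and by base-frequency bin.
#'
#' @param scored a data.frame from [score_experiment()] (columns
#'   `score`, `is_qtn`, `effect`, `base_freq`).
#' @param top_k size of the candidate list (default 2000).
#' @param effect_threshold strong/weak split (default 1).
#' @param freq_breaks interior breakpoints of the base-frequency bins
#'   (default `c(0.2, 0.8)`, giving bins f < 0.2, 0.2 <= f <= 0.8,
#'   f > 0.8).
#' @return list with `overall` (recovered fraction), `by_effect`,
#'   `by_freq` (recovered fraction per stratum) and the corresponding
#'   counts.
#' @export
qtn_recovery <- function(scored, top_k = 2000, effect_threshold = 1,
                         freq_breaks = c(0.2, 0.8)) {
  top_k <- min(top_k, nrow(scored))
  in_top <- logical(nrow(scored))
  in_top[order(-scored$score)[seq_len(top_k)]] <- TRUE
  q <- scored$is_qtn
  hit <- in_top & q
  eff_class <- ifelse(abs(scored$effect) > effect_threshold,
                      "strong", "weak")
  fbin <- ifelse(scored$base_freq < freq_breaks[1], "low",
                 ifelse(scored$base_freq <= freq_breaks[2], "mid", "high"))
  frac <- function(mask) {
    n <- sum(q & mask)
    if (n == 0) NA_real_ else sum(hit & mask) / n
  }
  list(
    overall = sum(hit) / sum(q),
    by_effect = c(strong = frac(q & eff_class == "strong"),
                  weak = frac(q & eff_class == "weak")),
    by_freq = c(low = frac(q & fbin == "low"),
                mid = frac(q & fbin == "mid"),
                high = frac(q & fbin == "high")),
    n_recovered = sum(hit), n_qtn = sum(q), top_k = top_k)
}
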