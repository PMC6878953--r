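test_that("pAUC hits the perfect, chance and inverted reference values", {
  # perfect separation: pAUC equals f_max
  scores <- c(rep(2, 10), rep(1, 1000))
  labels <- c(rep(TRUE, 10), rep(FALSE, 1000))
  expect_equal(roc_pauc(scores, labels, 0.01)$pauc, 0.01)
  # all scores tied: diagonal ROC, pAUC = f_max^2 / 2
  expect_equal(roc_pauc(rep(1, 1010), labels, 0.01)$pauc, 0.01^2 / 2)
  # perfectly inverted ranking: no positives before FPR = 1
  inv <- roc_pauc(-scores, labels, 0.01)
  expect_equal(inv$pauc, 0)
  # curve anchors
  r <- roc_pauc(scores, labels, 0.01)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_error(roc_pauc(1:5, rep(TRUE, 5)), "both classes")
  expect_error(roc_pauc(1:3, c(TRUE, FALSE)), "length mismatch")
})

test_that("pAUC matches an exhaustive threshold-sweep oracle", {
  brute_pauc <- function(scores, labels, f_max) {
    n_pos <- sum(labels); n_neg <- sum(!labels)
    th <- sort(unique(scores), decreasing = TRUE)
    fpr <- c(0, vapply(th, function(t) sum(scores[!labels] >= t), 0) / n_neg)
    tpr <- c(0, vapply(th, function(t) sum(scores[labels] >= t), 0) / n_pos)
    # explicit segment-by-segment trapezoid over the ROC polyline,
    # clipping the segment that crosses f_max
    area <- 0
    for (i in seq_len(length(fpr) - 1)) {
      x0 <- fpr[i]; x1 <- fpr[i + 1]
      y0 <- tpr[i]; y1 <- tpr[i + 1]
      if (x0 >= f_max) break
      if (x1 > f_max) {
        y1 <- y0 + (y1 - y0) * (f_max - x0) / (x1 - x0)
        x1 <- f_max
      }
      area <- area + (x1 - x0) * (y0 + y1) / 2
    }
    area
  }
  set.seed(60)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    scores <- sample(1:5, n, replace = TRUE)   # heavy ties on purpose
    f_max <- sample(c(0.1, 0.25, 0.5, 1), 1)
    expect_equal(roc_pauc(scores, labels, f_max)$pauc,
                 brute_pauc(scores, labels, f_max), tolerance = 1e-12)
  }
})

test_that("pAUC agrees with pROC on untied scores", {
  set.seed(61)
  labels <- c(rep(TRUE, 50), rep(FALSE, 500))
  scores <- rnorm(550, mean = ifelse(labels, 1, 0))
  mine <- roc_pauc(scores, labels, f_max = 0.01)$pauc
  oracle <- pROC::roc(response = labels, predictor = scores,
                      quiet = TRUE, direction = "<")
  pa <- pROC::auc(oracle, partial.auc = c(1, 0.99),
                  partial.auc.focus = "specificity")
  expect_equal(mine, as.numeric(pa), tolerance = 1e-10)
})

test_that("averaging identical curves reproduces them; pAUCs average linearly", {
  labels <- c(rep(TRUE, 20), rep(FALSE, 2000))
  set.seed(62)
  r1 <- roc_pauc(rnorm(2020, ifelse(labels, 2, 0)), labels, 0.01)
  r2 <- roc_pauc(rnorm(2020, ifelse(labels, 2, 0)), labels, 0.01)
  same <- average_roc(list(r1, r1, r1))
  expect_equal(same$mean_pauc, r1$pauc)
  # the averaged curve's own pAUC matches up to the FPR-grid resolution
  # (vertical steps are smeared over one grid interval)
  expect_equal(same$pauc, r1$pauc, tolerance = 0.05)
  avg <- average_roc(list(r1, r2))
  expect_equal(avg$mean_pauc, (r1$pauc + r2$pauc) / 2)
  expect_equal(avg$pauc_per_repetition, c(r1$pauc, r2$pauc))
  r3 <- roc_pauc(rnorm(2020), labels, 0.05)
  expect_error(average_roc(list(r1, r3)), "f_max")
})

test_that("consistency classes partition loci by replicate agreement", {
  dfreq <- rbind(
    c( 0.1,  0.2,  0.05,  0.3,  0.01),   # all positive -> hitchhiker
    c(-0.1, -0.2, -0.05, -0.3, -0.01),   # all negative -> hitchhiker
    c( 0.1,  0.2, -0.05, -0.3,  0.01),   # 3 vs 2 -> drift-like (k = 5)
    c( 0.1,  0.2,  0.05,  0.3, -0.01),   # 4 vs 1 -> inconsistent
    c( 0.1,  0.2,  0.05,  0.3,  0.0))    # a zero blocks hitchhiker; 4-0
  cls <- classify_consistency(dfreq, is_qtn = rep(FALSE, 5))
  expect_equal(cls, c("hitchhiker", "hitchhiker", "drift-like",
                      "inconsistent", "inconsistent"))
  # QTNs are labelled separately, regardless of pattern
  cls2 <- classify_consistency(dfreq, is_qtn = c(TRUE, rep(FALSE, 4)))
  expect_equal(cls2[1], "qtn")
  # the classes partition: every locus gets exactly one label
  set.seed(63)
  d <- matrix(rnorm(1000 * 10), 1000)
  cl <- classify_consistency(d, rep(FALSE, 1000))
  expect_true(all(cl %in% c("hitchhiker", "drift-like", "inconsistent")))
  # at k = 10, drift-like = majority 4:6; 5/5 split is drift-like
  d55 <- matrix(rep(c(1, -1), 5), 1)
  expect_equal(classify_consistency(d55, FALSE), "drift-like")
})

test_that("fixation timing is polarized to the selected allele and censored", {
  w <- tiny_world(n_hap = 100, n_loci = c(60, 60), n_qtn = 6)
  sch <- build_schedule(constant_regime(0.3), 30)
  st <- run_experiment(w$pool, w$arch, sch, w$map, N = 30,
                       k_replicates = 3, record_every = 5, seed = 64)
  fx <- fixation_stats(st, strong_threshold = 0.5)
  expect_equal(nrow(fx$per_qtn), 6 * 3)
  expect_true(all(fx$per_qtn$class %in% c("strong", "weak")))
  gens_ok <- is.na(fx$per_qtn$fixation_gen) |
    fx$per_qtn$fixation_gen %in% st$gens
  expect_true(all(gens_ok))
  # manual recomputation for one replicate
  twoN <- 2 * st$N
  for (qi in seq_along(st$arch$qtn_idx)) {
    tr <- st$counts[st$arch$qtn_idx[qi], , 1]
    sel <- if (st$arch$effects[qi] > 0) tr else twoN - tr
    expected <- if (any(sel == twoN)) st$gens[which(sel == twoN)[1]]
                else NA_real_
    got <- fx$per_qtn$fixation_gen[fx$per_qtn$replicate == 1][qi]
    expect_equal(got, expected)
  }
  expect_true(fx$prop_fixed >= 0 && fx$prop_fixed <= 1)
})

test_that("selection response is zero without selection pressure to act on", {
  w <- tiny_world(n_hap = 80, n_loci = c(40, 40), n_qtn = 4)
  st0 <- run_experiment(w$pool, w$arch, NULL, w$map, N = 50,
                        k_replicates = 2, seed = 65)
  expect_equal(selection_response(st0)$R, 0)
  # truncating selection on an h2 = 1 trait produces a positive response
  sch <- build_schedule(constant_regime(0.5), 15)
  st <- run_experiment(w$pool, w$arch, sch, w$map, N = 100,
                       k_replicates = 3, record_every = 15, seed = 66)
  resp <- selection_response(st)
  expect_length(resp$per_replicate, 3)
  expect_gt(resp$R, 0)
  expect_equal(resp$R, mean(resp$per_replicate))
})

test_that("QTN recovery stratifies by effect size and base frequency", {
  scored <- data.frame(
    score = c(10, 9, 8, 1, 0.5, 0.1),
    is_qtn = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    effect = c(2, 0.5, NA, -1.5, NA, 0.2),
    base_freq = c(0.1, 0.5, 0.3, 0.9, 0.4, 0.5))
  rec <- qtn_recovery(scored, top_k = 3, effect_threshold = 1)
  expect_equal(rec$overall, 2 / 4)
  expect_equal(rec$n_recovered, 2); expect_equal(rec$n_qtn, 4)
  expect_equal(unname(rec$by_effect["strong"]), 1 / 2)  # 2 & -1.5; 2 in top
  expect_equal(unname(rec$by_effect["weak"]), 1 / 2)    # 0.5 in, 0.2 out
  expect_equal(unname(rec$by_freq["low"]), 1)           # f = 0.1 recovered
  expect_equal(unname(rec$by_freq["mid"]), 1 / 2)
  expect_equal(unname(rec$by_freq["high"]), 0)          # f = 0.9 missed
  # top_k larger than the table recovers everything
  expect_equal(qtn_recovery(scored, top_k = 100)$overall, 1)
})
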