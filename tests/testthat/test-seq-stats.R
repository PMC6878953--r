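test_that("the CMH statistic matches the hand-computed single-stratum value", {
  # table: base (10, 10), evolved (15, 5); E = 12.5,
  # V = 20*20*25*15 / (40^2 * 39) = 2.40385; T = 6.25 / V = 2.6
  tab <- matrix(c(10, 15, 10, 5), 2, 2)
  res <- cmh_test(tab)
  E <- 20 * 25 / 40
  V <- 20 * 20 * 25 * 15 / (40^2 * 39)
  expect_equal(res$statistic, (10 - E)^2 / V)
  expect_equal(res$statistic, 2.6)
  expect_equal(res$p.value, pchisq(2.6, 1, lower.tail = FALSE))
})

test_that("the CMH statistic agrees with mantelhaen.test without correction", {
  set.seed(50)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    tab <- array(rpois(4 * k, 30) + 1, c(2, 2, k))
    res <- cmh_test(tab)
    oracle <- stats::mantelhaen.test(tab, correct = FALSE)
    expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, unname(oracle$p.value), tolerance = 1e-12)
  }
})

test_that("the CMH statistic is invariant to relabelling the columns", {
  set.seed(51)
  tab <- array(rpois(4 * 5, 40) + 1, c(2, 2, 5))
  swapped <- tab[, 2:1, ]
  expect_equal(cmh_test(tab)$statistic, cmh_test(swapped)$statistic)
})

test_that("degenerate strata are handled without NaN", {
  # a zero-margin stratum contributes nothing
  ok <- matrix(c(10, 15, 10, 5), 2, 2)
  zero_col <- matrix(c(10, 15, 0, 0), 2, 2)   # minor allele absent
  both <- simplify2array(list(ok, zero_col))
  expect_equal(cmh_test(both)$statistic, cmh_test(ok)$statistic)
  # all strata degenerate: zero total variance -> p = 1
  res <- cmh_test(zero_col)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_error(cmh_test(array(0, c(2, 2, 0))), "empty stratum")
  expect_error(cmh_test(array(0, c(2, 2, 2))), "positive total")
  expect_error(cmh_test(array(1, c(3, 2, 2))), "2 x 2 x k")
})

test_that("null CMH p-values on binomial tables are uniform", {
  set.seed(52)
  n_loci <- 2000; k <- 10; depth <- 500
  f <- runif(n_loci, 0.1, 0.9)
  p <- numeric(n_loci)
  A <- matrix(rbinom(n_loci * k, depth, f), n_loci, k)
  B <- depth - A
  C <- matrix(rbinom(n_loci * k, depth, f), n_loci, k)
  D <- depth - C
  res <- erpower:::cmh_core(A, B, C, D)
  expect_lt(abs(mean(res$p.value < 0.05) - 0.05), 0.015)
  ks <- suppressWarnings(ks.test(res$p.value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Pool-Seq sampling has binomial mean and an exact sentinel", {
  set.seed(53)
  f <- rep(0.3, 2e4)
  s <- poolseq_sample(f, 100)
  expect_equal(s$depth, 100L)
  expect_equal(mean(s$counts) / 100, 0.3, tolerance = 0.01)
  expect_true(all(s$counts >= 0 & s$counts <= 100))
  # fixed frequencies sample without noise
  expect_true(all(poolseq_sample(rep(0, 100), 50)$counts == 0))
  expect_true(all(poolseq_sample(rep(1, 100), 50)$counts == 50))
  # exact mode returns the true counts unchanged
  ex <- poolseq_sample(c(0.25, 0.5), Inf, true_counts = c(5, 10),
                       true_depth = 20)
  expect_identical(ex$counts, c(5L, 10L))
  expect_identical(ex$depth, 20L)
  expect_error(poolseq_sample(c(-0.1), 10), "\\[0, 1\\]")
  expect_error(poolseq_sample(0.5, 0.5), "coverage")
})

test_that("scoring a zero-generation experiment finds nothing", {
  w <- tiny_world(n_hap = 80, n_loci = c(50, 50), n_qtn = 5)
  st <- run_experiment(w$pool, w$arch, NULL, w$map, N = 50,
                       k_replicates = 3, seed = 54)
  scored <- score_experiment(st)
  # base and evolved are the same sample: every table is homogeneous
  expect_true(all(scored$p_value == 1))
  expect_true(all(scored$score == 0))
  expect_equal(sum(scored$is_qtn), 5)
  expect_true(all(attr(scored, "dfreq") == 0))
})

test_that("score_experiment matches a per-locus mantelhaen.test loop", {
  w <- tiny_world(n_hap = 80, n_loci = c(40, 40), n_qtn = 8)
  sch <- build_schedule(constant_regime(0.5), 8)
  st <- run_experiment(w$pool, w$arch, sch, w$map, N = 50,
                       k_replicates = 3, record_every = 8, seed = 55)
  scored <- score_experiment(st)
  twoN <- 100L
  d0 <- st$counts[, 1, 1]
  for (i in c(1, 7, 20, 41, 80)) {
    major_derived <- d0[i] / twoN > 0.5
    tabs <- lapply(1:3, function(r) {
      dT <- st$counts[i, length(st$gens), r]
      b <- c(d0[i], twoN - d0[i]); e <- c(dT, twoN - dT)
      if (!major_derived) { b <- rev(b); e <- rev(e) }
      rbind(b, e)
    })
    arr <- simplify2array(tabs)
    skip_locus <- all(apply(arr, 3, function(m) any(colSums(m) == 0)))
    if (skip_locus) {
      expect_equal(scored$p_value[i], 1)
    } else if (all(apply(arr, 3, function(m) all(colSums(m) > 0)))) {
      oracle <- stats::mantelhaen.test(arr, correct = FALSE)
      expect_equal(scored$p_value[i], unname(oracle$p.value),
                   tolerance = 1e-10)
    }
  }
  # dfreq is polarized to the base minor allele and bounded
  dfreq <- attr(scored, "dfreq")
  expect_equal(dim(dfreq), c(80, 3))
  expect_true(all(abs(dfreq) <= 1))
})

test_that("Pool-Seq noise weakens but does not bias the scan", {
  w <- tiny_world(n_hap = 100, n_loci = c(60, 60), n_qtn = 6)
  sch <- build_schedule(constant_regime(0.5), 10)
  st <- run_experiment(w$pool, w$arch, sch, w$map, N = 60,
                       k_replicates = 3, record_every = 10, seed = 56)
  set.seed(57)
  noisy <- score_experiment(st, coverage = 80)
  exact <- score_experiment(st)
  expect_equal(nrow(noisy), nrow(exact))
  expect_false(identical(noisy$p_value, exact$p_value))
  expect_true(all(noisy$p_value >= 0 & noisy$p_value <= 1))
})

test_that("sync files round-trip counts in A:T:C:G:N:del format", {
  loci <- data.frame(chrom = c("2L", "2L", "3R"), pos = c(100, 250, 7),
                     stringsAsFactors = FALSE)
  samples <- list(cbind(c(1900L, 30L, 0L), c(100L, 10L, 40L)),
                  cbind(c(5L, 6L, 7L), c(0L, 1L, 2L)))
  path <- withr::local_tempfile(fileext = ".sync")
  write_sync(loci, samples, path)
  lines <- readLines(path)
  expect_equal(lines[1], "2L\t100\tN\t1900:100:0:0:0:0\t5:0:0:0:0:0")
  back <- read_sync(path)
  expect_equal(back$loci$chrom, loci$chrom)
  expect_equal(back$loci$pos, loci$pos)
  expect_equal(back$samples[[1]], unname(samples[[1]]))
  expect_equal(back$samples[[2]], unname(samples[[2]]))
  # empty input round-trips to an empty result
  write_sync(loci[0, ], list(), path)
  expect_equal(nrow(read_sync(path)$loci), 0)
  writeLines(c("2L\t1\tN\t1:0:0:0:0:0", "2L\t2\tN"), path)
  expect_error(read_sync(path), "ragged")
})

test_that("store export writes base first, then replicate-major samples", {
  w <- tiny_world(n_hap = 60, n_loci = c(30, 30), n_qtn = 4)
  sch <- build_schedule(constant_regime(0.5), 10)
  st <- run_experiment(w$pool, w$arch, sch, w$map, N = 40,
                       k_replicates = 2, record_every = 5, seed = 58)
  path <- withr::local_tempfile(fileext = ".sync")
  write_sync_from_store(st, path)
  back <- read_sync(path)
  # 1 base + 2 replicates x 2 recorded later generations
  expect_length(back$samples, 1 + 2 * 2)
  expect_equal(back$samples[[1]][, 2], unname(st$counts[, 1, 1]))
  expect_equal(back$samples[[2]][, 2], unname(st$counts[, 2, 1]))
  expect_equal(back$samples[[4]][, 2], unname(st$counts[, 2, 2]))
  expect_true(all(rowSums(back$samples[[1]]) == 2 * st$N))
})
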