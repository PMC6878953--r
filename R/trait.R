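#' Effect-size distribution specifications
#'
#' `effect_gamma()` describes gamma-distributed absolute effect sizes
#' (the classic "few large, many small" architecture seen in QTL
#' studies; the default trait uses shape 0.42, scale 1);
#' `effect_equal()` gives every causative locus the same absolute
#' effect.
#'
#' @param shape,scale gamma parameters for `|a|`.
#' @param value common absolute effect for the equal-effects trait.
#' @return a list describing the distribution, for use in
#'   [draw_architecture()].
#' @export
effect_gamma <- function(shape = 0.42, scale = 1) {
  if (shape <= 0 || scale <= 0) stop("gamma shape and scale must be > 0")
  structure(list(kind = "gamma", shape = shape, scale = scale),
            class = "effect_distribution")
}

#' @rdname effect_gamma
#' @export
effect_equal <- function(value = 1) {
  if (value <= 0) stop("effect value must be > 0")
  structure(list(kind = "equal", value = value),
            class = "effect_distribution")
}

draw_effect_sizes <- function(dist, n) {
  switch(dist$kind,
         gamma = rgamma(n, shape = dist$shape, scale = dist$scale),
         equal = rep(dist$value, n),
         stop("unknown effect distribution kind: ", dist$kind))
}

#' Draw a quantitative trait architecture
#'
#' Samples `n_qtn` causative loci (QTNs) uniformly without replacement
#' among pool loci whose derived-allele frequency lies within
#' `freq_bounds`, draws absolute effect sizes from the given
#' distribution, flips the sign of each effect with probability 1/2, and
#' calibrates the environmental variance so that the base-population
#' heritability equals `h2`. The derived allele (matrix value 1)
#' carries the effect `a` per copy.
#'
#' The genotypic variance `Vg0` is the additive variance implied by the
#' pool frequencies under random pairing of haplotypes (linkage
#' equilibrium): `Vg0 = sum(2 p q a^2)`.
#'
#' @param pool a `haplotype_pool`.
#' @param n_qtn number of causative loci (default 100).
#' @param effect_distribution an [effect_gamma()] or [effect_equal()]
#'   specification.
#' @param freq_bounds numeric length-2, eligible base-frequency range
#'   (default `c(0.05, 0.95)`), so all QTNs contribute at least
#'   moderately to the genetic variance.
#' @param h2 narrow-sense heritability in `(0, 1]` of the base
#'   population.
#' @param seed optional integer seed.
#' @return An object of class `trait_architecture`: list with
#'   `qtn_idx` (locus indices), `effects` (signed, trait units per copy
#'   of the derived allele), `base_freq`, `h2`, `Vg0`, `Ve`.
#' @export
draw_architecture <- function(pool, n_qtn = 100,
                              effect_distribution = effect_gamma(0.42, 1),
                              freq_bounds = c(0.05, 0.95), h2 = 1,
                              seed = NULL) {
  f <- pool_frequencies(pool)
  eligible <- which(f >= freq_bounds[1] & f <= freq_bounds[2])
  if (length(eligible) < n_qtn)
    stop("only ", length(eligible), " loci within frequency bounds, need ",
         n_qtn)
  with_seed(seed, {
    qtn <- sort(sample(eligible, n_qtn))
    a <- draw_effect_sizes(effect_distribution, n_qtn)
    sign_flip <- sample(c(-1, 1), n_qtn, replace = TRUE)
    effects <- a * sign_flip
    p <- f[qtn]
    Vg0 <- sum(2 * p * (1 - p) * effects^2)
    Ve <- calibrate_env_variance(Vg0, h2)
    structure(list(qtn_idx = qtn, effects = effects, base_freq = p,
                   h2 = h2, Vg0 = Vg0, Ve = Ve,
                   freq_bounds = freq_bounds,
                   loci = pool$loci[qtn, , drop = FALSE]),
              class = "trait_architecture")
  })
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("<trait_architecture> ", length(x$qtn_idx), " QTNs, h2 = ", x$h2,
      ", Vg0 = ", signif(x$Vg0, 4), ", Ve = ", signif(x$Ve, 4), "\n",
      sep = "")
  invisible(x)
}

#' Additive genotypic values
#'
#' `G_j = sum_i dosage_ji * a_i`, purely additive (no dominance or
#' epistasis).
#'
#' @param dosages integer matrix (individuals x QTNs) of derived-allele
#'   dosages in `{0, 1, 2}`.
#' @param arch a `trait_architecture`.
#' @return numeric vector of genotypic values (trait units).
#' @export
genotypic_values <- function(dosages, arch) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(arch$effects))
    stop("dosage matrix has ", ncol(dosages), " columns, expected ",
         length(arch$effects))
  if (any(!dosages %in% c(0, 1, 2)))
    stop("dosages must be in {0, 1, 2}")
  drop(dosages %*% arch$effects)
}

#' Calibrate the environmental variance for a target heritability
#'
#' `Ve = Vg0 (1 - h2) / h2`, so that `Vg0 / (Vg0 + Ve) = h2` in the base
#' population. With `h2 = 1` the phenotype equals the genotypic value
#' (1:1 genotype-to-phenotype mapping).
#'
#' @param Vg0 genotypic variance of the base population (trait units^2).
#' @param h2 heritability in `(0, 1]`.
#' @return environmental variance `Ve` (trait units^2).
#' @export
calibrate_env_variance <- function(Vg0, h2) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  if (Vg0 < 0) stop("Vg0 must be >= 0")
  Vg0 * (1 - h2) / h2
}

#' Draw phenotypes from genotypic values
#'
#' `P_j = G_j + e_j` with `e_j ~ Normal(0, Ve)` drawn independently,
#' fresh for each generation.
#'
#' @param G numeric vector of genotypic values.
#' @param Ve environmental variance (>= 0).
#' @return numeric vector of phenotypes.
#' @export
phenotype_individuals <- function(G, Ve) {
  if (Ve < 0) stop("Ve must be >= 0")
  if (Ve == 0) return(G)
  G + rnorm(length(G), 0, sqrt(Ve))
}

#' Write / read a trait architecture as TSV
#'
#' One row per QTN (`chrom`, `pos`, `effect`, `base_frequency`) plus a
#' comment header holding `h2`, `Vg0` and `Ve`.
#'
#' @param arch a `trait_architecture`.
#' @param path file path.
#' @export
write_architecture <- function(arch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#erarch v1 h2=%.17g Vg0=%.17g Ve=%.17g",
                     arch$h2, arch$Vg0, arch$Ve), con)
  writeLines("chrom\tpos\teffect\tbase_frequency", con)
  writeLines(sprintf("%s\t%d\t%.17g\t%.17g", arch$loci$chrom,
                     arch$loci$pos, arch$effects, arch$base_freq), con)
  invisible(path)
}
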