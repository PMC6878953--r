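#' Found a diploid base population from a haplotype pool
#'
#' Samples `2N` haplotypes uniformly with replacement from the pool and
#' pairs them into `N` diploid individuals. Re-using the same seeded
#' draw lets every replicate of an experiment start from the identical
#' base population, the convention used by [run_experiment()].
#'
#' @param pool a `haplotype_pool`.
#' @param N number of diploid individuals.
#' @param seed optional integer seed.
#' @return An object of class `er_population`: list with `haps`
#'   (integer matrix, loci x 2N; columns `2i-1`, `2i` belong to
#'   individual `i`), `loci`, and `generation = 0`.
#' @export
found_population <- function(pool, N, seed = NULL) {
  if (nrow(pool$alleles) < 1) stop("pool is empty")
  with_seed(seed, {
    idx <- sample.int(nrow(pool$alleles), 2 * N, replace = TRUE)
    haps <- t(pool$alleles[idx, , drop = FALSE])
    storage.mode(haps) <- "integer"
    structure(list(haps = haps, loci = pool$loci, generation = 0L),
              class = "er_population")
  })
}

#' @export
print.er_population <- function(x, ...) {
  cat("<er_population> ", ncol(x$haps) / 2, " diploids, ",
      nrow(x$haps), " loci, generation ", x$generation, "\n", sep = "")
  invisible(x)
}

#' Simulate gametes of one individual
#'
#' Haldane crossover model: per chromosome the number of crossovers is
#' Poisson with mean equal to the chromosome's genetic length (Morgans,
#' after any map halving), crossover positions fall uniformly on the
#' genetic scale, the starting strand is chosen with probability 1/2,
#' and chromosomes assort independently.
#'
#' @param individual integer matrix (loci x 2), the two haplotypes of
#'   one individual.
#' @param map a `recomb_map` covering all loci.
#' @param loci data.frame with `chrom`, `pos` for each row of
#'   `individual`.
#' @param n number of gametes to draw.
#' @return integer matrix (loci x n) of gamete haplotypes.
#' @export
make_gametes <- function(individual, map, loci, n = 1) {
  mi <- map_index(loci, map)
  storage.mode(individual) <- "integer"
  cpp_make_gametes(individual, as.integer(n), mi$chrom_start, mi$gpos,
                   mi$glen)
}

# dosage matrix (n_qtn x N) and genotypic values from a haplotype matrix
qtn_genotypes <- function(haps, qtn_idx) {
  h <- haps[qtn_idx, , drop = FALSE]
  n2 <- ncol(h)
  h[, seq(1, n2, by = 2), drop = FALSE] +
    h[, seq(2, n2, by = 2), drop = FALSE]
}

# one selection + reproduction step on a raw haplotype matrix.
# Returns list(haps, G, P): G and P are the pre-selection genotypic
# values and phenotypes of the *input* population.
step_generation <- function(haps, arch, fraction, mi) {
  N <- ncol(haps) / 2
  dos <- qtn_genotypes(haps, arch$qtn_idx)
  G <- drop(crossprod(dos, arch$effects))
  P <- phenotype_individuals(G, arch$Ve)
  nsel <- n_selected(N, fraction)
  sel <- order(-P, runif(N))[seq_len(nsel)]   # ties broken at random
  p1 <- sel[sample.int(nsel, N, replace = TRUE)]
  p2 <- sel[sample.int(nsel, N, replace = TRUE)]
  bad <- which(p1 == p2)                      # no selfing: distinct parents
  while (length(bad)) {
    p2[bad] <- sel[sample.int(nsel, length(bad), replace = TRUE)]
    bad <- bad[p1[bad] == p2[bad]]
  }
  new_haps <- cpp_next_generation(haps, as.integer(p1), as.integer(p2),
                                  mi$chrom_start, mi$gpos, mi$glen)
  list(haps = new_haps, G = G, P = P)
}

#' Advance a population by one generation of truncating selection
#'
#' Phenotypes are computed from the trait architecture, the top
#' `fraction_selected` of individuals by phenotype are retained (ties
#' broken uniformly at random), and `N` offspring are produced, each
#' from two distinct parents drawn uniformly with replacement from the
#' selected set, one gamete per parent. `fraction_selected = 1` gives
#' pure drift under random mating.
#'
#' @param pop an `er_population`.
#' @param arch a `trait_architecture`.
#' @param fraction_selected fraction in `(0, 1]`.
#' @param map a `recomb_map`.
#' @return the next-generation `er_population` (same size `N`).
#' @export
advance_generation <- function(pop, arch, fraction_selected, map) {
  if (fraction_selected <= 0 || fraction_selected > 1)
    stop("fraction_selected must be in (0, 1]")
  mi <- map_index(pop$loci, map)
  st <- step_generation(pop$haps, arch, fraction_selected, mi)
  structure(list(haps = st$haps, loci = pop$loci,
                 generation = pop$generation + 1L),
            class = "er_population")
}

#' Run a replicated E&R experiment
#'
#' Evolves `k_replicates` independent replicates from an identical
#' founded base population under a truncating-selection schedule.
#' Selection is applied in generations `0 .. n-1`; the final sequencing
#' timepoint is generation `n` (the offspring of the last selection
#' episode). Derived-allele counts are recorded at generation 0, every
#' `record_every` generations, and the final generation; phenotype and
#' genotypic-value mean/variance are recorded every generation. No de
#' novo mutation occurs, so counts are absorbing at 0 and `2N`.
#'
#' Replicate RNG streams are derived deterministically from `seed` and
#' the replicate index, so the same seed and configuration reproduce the
#' trajectory store bit for bit.
#'
#' @param pool a `haplotype_pool`.
#' @param arch a `trait_architecture` drawn on that pool.
#' @param schedule a `selection_schedule` (its length sets the number of
#'   generations; length 0 is allowed and records only generation 0).
#' @param map a `recomb_map`.
#' @param N diploid population size (default 1000).
#' @param k_replicates number of replicates (default 10).
#' @param record_every record allele counts every this many generations
#'   (default 10).
#' @param seed integer seed.
#' @return An object of class `trajectory_store`: list with `counts`
#'   (integer array loci x timepoints x replicates of derived-allele
#'   counts out of `2N`), `gens` (recorded generations), `pheno`
#'   (data.frame: replicate, generation, mean_G, var_G, mean_P, var_P),
#'   `N`, `k`, `arch`, `loci`, `schedule_label`.
#' @export
run_experiment <- function(pool, arch, schedule, map, N = 1000,
                           k_replicates = 10, record_every = 10,
                           seed = 1) {
  fractions <- if (is.null(schedule)) numeric(0) else schedule$fractions
  n_gen <- length(fractions)
  mi <- map_index(pool$loci, map)
  record_gens <- unique(c(0, seq(0, n_gen, by = max(1, record_every)),
                          n_gen))
  record_gens <- sort(record_gens[record_gens <= n_gen])

  base <- found_population(pool, N, seed = derive_seed(seed, 0))
  k <- k_replicates
  n_loci <- nrow(pool$loci)
  counts <- array(0L, dim = c(n_loci, length(record_gens), k))
  pheno <- vector("list", k)

  for (r in seq_len(k)) {
    set.seed(derive_seed(seed, r))
    haps <- base$haps
    ph <- data.frame(replicate = r, generation = 0:n_gen,
                     mean_G = NA_real_, var_G = NA_real_,
                     mean_P = NA_real_, var_P = NA_real_)
    ti <- 1L
    for (g in 0:n_gen) {
      if (g %in% record_gens) {
        counts[, ti, r] <- cpp_allele_counts(haps)
        ti <- ti + 1L
      }
      if (g < n_gen) {
        st <- step_generation(haps, arch, fractions[g + 1], mi)
        haps <- st$haps
        G <- st$G; P <- st$P
      } else {
        dos <- qtn_genotypes(haps, arch$qtn_idx)
        G <- drop(crossprod(dos, arch$effects))
        P <- phenotype_individuals(G, arch$Ve)
      }
      ph[g + 1, 3:6] <- c(mean(G), var(G), mean(P), var(P))
    }
    pheno[[r]] <- ph
  }
  structure(list(counts = counts, gens = record_gens,
                 pheno = do.call(rbind, pheno), N = N, k = k,
                 arch = arch, loci = pool$loci,
                 schedule_label = if (is.null(schedule)) "none"
                                  else schedule$label,
                 seed = seed),
            class = "trajectory_store")
}

#' @export
print.trajectory_store <- function(x, ...) {
  cat("<trajectory_store> ", x$k, " replicates, N = ", x$N,
      ", schedule ", x$schedule_label, ", recorded generations: ",
      paste(x$gens, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Write trajectories as TSV (replicate, generation, locus, count)
#' @param store a `trajectory_store`.
#' @param path file path.
#' @export
write_trajectories <- function(store, path) {
  n_loci <- dim(store$counts)[1]
  rows <- expand.grid(locus = seq_len(n_loci),
                      generation = store$gens,
                      replicate = seq_len(store$k))
  df <- data.frame(replicate = rows$replicate,
                   generation = rows$generation, locus = rows$locus,
                   count = as.vector(store$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Phenotype summaries of a store as a data.frame
#' @param store a `trajectory_store`.
#' @export
phenotype_summary <- function(store) store$pheno
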