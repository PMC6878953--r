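#' Experiment configuration
#'
#' Bundles all design parameters of a replicated E&R study. The defaults
#' are the canonical design: `N = 1000` diploids, 100 QTNs, 90
#' generations, 10 replicates, gamma(0.42, 1) effect sizes, `h2 = 1`,
#' and 10 repetitions (independent QTN sets). Unknown fields are
#' rejected.
#'
#' @param N diploid population size.
#' @param n_qtn number of causative loci.
#' @param generations generations of selection.
#' @param replicates replicate populations per repetition.
#' @param effect_distribution an [effect_gamma()] / [effect_equal()]
#'   spec.
#' @param h2 heritability in `(0, 1]`.
#' @param repetitions independent QTN sets.
#' @param record_every allele-count recording interval (generations).
#' @param coverage Pool-Seq depth, `Inf` = exact counts.
#' @param freq_bounds QTN base-frequency bounds.
#' @param f_max pAUC cutoff.
#' @param min_recomb_rate optional rate threshold (cM/Mb); loci in
#'   windows below it are excluded from scoring.
#' @return validated list of class `er_config`.
#' @export
er_config <- function(N = 1000, n_qtn = 100, generations = 90,
                      replicates = 10,
                      effect_distribution = effect_gamma(0.42, 1),
                      h2 = 1, repetitions = 10, record_every = 10,
                      coverage = Inf, freq_bounds = c(0.05, 0.95),
                      f_max = 0.01, min_recomb_rate = NULL) {
  cfg <- list(N = N, n_qtn = n_qtn, generations = generations,
              replicates = replicates,
              effect_distribution = effect_distribution, h2 = h2,
              repetitions = repetitions, record_every = record_every,
              coverage = coverage, freq_bounds = freq_bounds,
              f_max = f_max, min_recomb_rate = min_recomb_rate)
  validate_config(cfg)
}

#' @rdname er_config
#' @param x a named list of configuration fields.
#' @export
as_er_config <- function(x) {
  known <- names(formals(er_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(er_config, x)
}

validate_config <- function(cfg) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid config field '", field, "': ", msg)
  }
  chk(cfg$N >= 2, "N", "must be >= 2")
  chk(cfg$n_qtn >= 1, "n_qtn", "must be >= 1")
  chk(cfg$generations >= 0, "generations", "must be >= 0")
  chk(cfg$replicates >= 1, "replicates", "must be >= 1")
  chk(inherits(cfg$effect_distribution, "effect_distribution"),
      "effect_distribution", "must be effect_gamma()/effect_equal()")
  chk(cfg$h2 > 0 && cfg$h2 <= 1, "h2", "must be in (0, 1]")
  chk(cfg$repetitions >= 1, "repetitions", "must be >= 1")
  chk(cfg$record_every >= 1, "record_every", "must be >= 1")
  chk(is.infinite(cfg$coverage) || cfg$coverage >= 1, "coverage",
      "must be >= 1 or Inf")
  chk(length(cfg$freq_bounds) == 2 && cfg$freq_bounds[1] <
        cfg$freq_bounds[2], "freq_bounds", "must be an increasing pair")
  chk(cfg$f_max > 0 && cfg$f_max <= 1, "f_max", "must be in (0, 1]")
  structure(cfg, class = "er_config")
}

#' Run a full E&R power study
#'
#' For each repetition a fresh trait architecture is drawn, the
#' replicated experiment is simulated, loci are scored with the CMH
#' test, and detection power (ROC/pAUC) and the phenotypic response are
#' evaluated. Architecture seeds depend only on the master seed and the
#' repetition index, so studies run under different selection schedules
#' with the same seed share the same QTN sets (paired comparisons).
#'
#' @param pool a `haplotype_pool`.
#' @param map a `recomb_map`.
#' @param schedule a `selection_schedule` with `config$generations`
#'   entries (or `NULL` for a zero-generation study).
#' @param config an [er_config()].
#' @param seed master integer seed.
#' @param out_dir optional output directory; when given, per-repetition
#'   score tables, a JSON summary and a manifest with content digests
#'   are written.
#' @return list with `pauc` (per-repetition pAUCs), `mean_pauc`, `R`
#'   (per-repetition mean responses), `mean_R`, `avg_roc`,
#'   `recovery` (per-repetition QTN recovery), `label`.
#' @export
run_er_study <- function(pool, map, schedule, config = er_config(),
                         seed = 1, out_dir = NULL) {
  config <- validate_config(config)
  if (!is.null(schedule) &&
      length(schedule$fractions) != config$generations)
    stop("schedule length (", length(schedule$fractions),
         ") != config$generations (", config$generations, ")")
  keep <- if (!is.null(config$min_recomb_rate))
    !flag_low_recomb(pool, map, config$min_recomb_rate)
  else rep(TRUE, nrow(pool$loci))

  paucs <- numeric(config$repetitions)
  Rs <- numeric(config$repetitions)
  rocs <- vector("list", config$repetitions)
  recov <- vector("list", config$repetitions)
  files <- character(0)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  for (rep_i in seq_len(config$repetitions)) {
    arch <- draw_architecture(pool, config$n_qtn,
                              config$effect_distribution,
                              config$freq_bounds, config$h2,
                              seed = derive_seed(seed, rep_i, 1))
    store <- run_experiment(pool, arch, schedule, map, N = config$N,
                            k_replicates = config$replicates,
                            record_every = config$record_every,
                            seed = derive_seed(seed, rep_i, 2))
    scored <- with_seed(derive_seed(seed, rep_i, 3),
                        score_experiment(store, config$coverage))
    sc <- scored[keep, , drop = FALSE]
    rocs[[rep_i]] <- roc_pauc(sc$score, sc$is_qtn, config$f_max)
    paucs[rep_i] <- rocs[[rep_i]]$pauc
    Rs[rep_i] <- selection_response(store)$R
    recov[[rep_i]] <- qtn_recovery(sc)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, sprintf("scores_rep%02d.tsv", rep_i))
      write.table(scored, f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f)
    }
  }
  res <- list(pauc = paucs, mean_pauc = mean(paucs), R = Rs,
              mean_R = mean(Rs), avg_roc = average_roc(rocs),
              recovery = recov,
              label = if (is.null(schedule)) "none" else schedule$label)
  if (!is.null(out_dir)) {
    sf <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(label = res$label, pauc = paucs, mean_pauc = res$mean_pauc,
           R = Rs, mean_R = res$mean_R, seed = seed,
           config = config[c("N", "n_qtn", "generations", "replicates",
                             "h2", "repetitions", "record_every",
                             "f_max")]),
      sf, auto_unbox = TRUE, digits = NA)
    files <- c(files, sf)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  res
}

#' Sweep selection regimes and rank them
#'
#' Runs [run_er_study()] for every schedule in the grid under a shared
#' configuration and master seed (so all regimes see the same QTN sets)
#' and ranks the regimes twice: by mean pAUC (the regime best at
#' identifying causative loci) and by mean phenotypic response R (the
#' regime best at shifting the phenotype). The two rankings are
#' permutations of the same regime set and typically disagree.
#'
#' @param pool a `haplotype_pool`.
#' @param map a `recomb_map`.
#' @param schedules list of `selection_schedule`s (e.g.
#'   [regime_grid()]).
#' @param config an [er_config()].
#' @param seed master seed.
#' @return list with `by_pauc` and `by_R` (data.frames sorted best
#'   first) and `results` (per-schedule [run_er_study()] outputs).
#' @export
sweep_regimes <- function(pool, map, schedules, config = er_config(),
                          seed = 1) {
  results <- lapply(schedules, function(s)
    run_er_study(pool, map, s, config, seed))
  df <- data.frame(
    label = vapply(results, function(r) r$label, ""),
    mean_pauc = vapply(results, function(r) r$mean_pauc, 0),
    mean_R = vapply(results, function(r) r$mean_R, 0),
    stringsAsFactors = FALSE)
  list(by_pauc = df[order(-df$mean_pauc), ],
       by_R = df[order(-df$mean_R), ],
       results = results)
}
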