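#' Truncating-selection schedules
#'
#' A selection schedule gives, for each generation, the fraction of
#' individuals retained as parents (smaller fraction = stronger
#' truncating selection). `constant_regime(p)` keeps the fraction fixed;
#' `linear_regime(p_start, p_end)` interpolates linearly over the
#' generation index so that both endpoints are attained exactly
#' (`p_start` at generation 0, `p_end` at the last selected
#' generation). A regime whose selected fraction decreases with time is
#' a regime of *increasing* selection strength.
#'
#' @param p,p_start,p_end selected fractions in `(0, 1]`.
#' @return a regime specification for [build_schedule()].
#' @export
constant_regime <- function(p) {
  stopifnot(p > 0, p <= 1)
  structure(list(kind = "constant", p = p), class = "regime_spec")
}

#' @rdname constant_regime
#' @export
linear_regime <- function(p_start, p_end) {
  stopifnot(p_start > 0, p_start <= 1, p_end > 0, p_end <= 1)
  structure(list(kind = "linear", p_start = p_start, p_end = p_end),
            class = "regime_spec")
}

#' Build a selection schedule
#'
#' @param kind a [constant_regime()] or [linear_regime()] specification.
#' @param n_generations number of generations of selection (>= 1).
#' @return An object of class `selection_schedule`: list with
#'   `fractions` (length `n_generations`, each in `(0, 1]`) and a
#'   human-readable `label` (`"const50"` or `"90->10"`, percentages).
#' @export
build_schedule <- function(kind, n_generations) {
  if (n_generations < 1) stop("n_generations must be >= 1")
  fr <- switch(kind$kind,
    constant = rep(kind$p, n_generations),
    linear = {
      if (n_generations == 1) kind$p_start
      else {
        g <- seq_len(n_generations) - 1
        kind$p_start + (kind$p_end - kind$p_start) * g / (n_generations - 1)
      }
    },
    stop("unknown regime kind"))
  if (any(fr <= 0) || any(fr > 1))
    stop("selected fractions must lie in (0, 1]")
  label <- switch(kind$kind,
    constant = sprintf("const%g", 100 * kind$p),
    linear = sprintf("%g->%g", 100 * kind$p_start, 100 * kind$p_end))
  structure(list(fractions = fr, label = label, kind = kind),
            class = "selection_schedule")
}

#' @export
print.selection_schedule <- function(x, ...) {
  cat("<selection_schedule> ", x$label, ", ", length(x$fractions),
      " generations\n", sep = "")
  invisible(x)
}

#' Number of individuals selected at a given fraction
#'
#' Rounds `N * p` to the nearest integer (half away from zero) and
#' clamps to `[2, N]`, so a breeding pair always remains.
#'
#' @param N population size (>= 2).
#' @param p selected fraction in `(0, 1]`.
#' @return integer count of selected individuals.
#' @export
n_selected <- function(N, p) {
  if (N < 2) stop("N must be >= 2")
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  as.integer(pmin(N, pmax(2, floor(N * p + 0.5))))
}

#' Grid of constant and increasing-strength regimes
#'
#' All constant schedules at fractions `step, 2*step, ..., 1 - step` and
#' all linear schedules with strictly decreasing selected fraction
#' (increasing selection strength) between endpoints from the same set.
#' With the default step of 0.1 this yields 9 constant plus 36
#' increasing regimes (45 schedules). Regimes of decreasing strength
#' can be built with [linear_regime()] directly but are excluded from
#' the default sweep.
#'
#' @param step grid step for the selected fraction (default 0.1).
#' @param n_generations schedule length.
#' @return list of `selection_schedule` objects.
#' @export
regime_grid <- function(step = 0.1, n_generations) {
  ps <- seq(step, 1 - step, by = step)
  ps <- round(ps, 10)
  out <- lapply(ps, function(p) build_schedule(constant_regime(p),
                                               n_generations))
  for (i in rev(seq_along(ps))) {
    for (j in seq_along(ps)) {
      if (ps[i] > ps[j])
        out[[length(out) + 1]] <- build_schedule(
          linear_regime(ps[i], ps[j]), n_generations)
    }
  }
  out
}

#' Write a schedule as TSV (generation, fraction)
#' @param schedule a `selection_schedule`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  df <- data.frame(generation = seq_along(schedule$fractions) - 1,
                   fraction = schedule$fractions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#erschedule v1 label=", schedule$label), con)
  writeLines("generation\tfraction", con)
  writeLines(sprintf("%d\t%.17g", df$generation, df$fraction), con)
  invisible(path)
}
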