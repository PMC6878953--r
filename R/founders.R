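#' Generate a synthetic founder haplotype pool
#'
#' Creates a pool of phased binary haplotypes whose site frequency
#' spectrum follows `i^(-spectrum_exponent)` over derived-allele counts
#' `i` (exponent 1 is the standard neutral spectrum). Derived alleles are
#' assigned to haplotypes uniformly at random, so the pool starts in
#' linkage equilibrium. Such a pool plays the role of a panel of
#' sequenced inbred (homozygous) founder lines: each line donates one
#' haplotype.
#'
#' @param n_haplotypes number of founder haplotypes (>= 2).
#' @param n_loci_per_chromosome integer vector, number of polymorphic
#'   loci on each chromosome.
#' @param chromosome_lengths named numeric vector of chromosome lengths
#'   in base pairs; names become chromosome ids (defaults to
#'   `"chr1"`, `"chr2"`, ...).
#' @param maf_min minimum minor-allele frequency in the pool
#'   (`0 <= maf_min < 0.5`); every locus is kept within
#'   `[maf_min, 1 - maf_min]`.
#' @param spectrum_exponent exponent of the frequency spectrum weights
#'   `i^(-exponent)`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#'
#' @return An object of class `haplotype_pool`: a list with `alleles`
#'   (integer 0/1 matrix, haplotypes in rows, loci in columns), `loci`
#'   (data.frame with `chrom`, `pos`; positions 1-based, strictly
#'   increasing within chromosome) and `chrom_len` (named vector, bp).
#' @export
generate_founders <- function(n_haplotypes, n_loci_per_chromosome,
                              chromosome_lengths, maf_min = 0.05,
                              spectrum_exponent = 1, seed = NULL) {
  if (n_haplotypes < 2) stop("n_haplotypes must be >= 2")
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)")
  if (length(n_loci_per_chromosome) != length(chromosome_lengths))
    stop("n_loci_per_chromosome and chromosome_lengths differ in length")
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  n <- as.integer(n_haplotypes)

  # allowed derived counts under the minor-allele frequency bound
  lo <- max(1L, as.integer(ceiling(maf_min * n - 1e-9)))
  hi <- min(n - 1L, as.integer(floor((1 - maf_min) * n + 1e-9)))
  if (lo > hi)
    stop("maf_min = ", maf_min, " is infeasible for ", n, " haplotypes")
  counts_allowed <- lo:hi
  w <- counts_allowed^(-spectrum_exponent)

  with_seed(seed, {
    loci_list <- vector("list", length(chromosome_lengths))
    for (c in seq_along(chromosome_lengths)) {
      m <- as.integer(n_loci_per_chromosome[c])
      len <- chromosome_lengths[c]
      if (m > len)
        stop("chromosome ", names(chromosome_lengths)[c], ": requested ",
             m, " loci but only ", len, " distinct positions available")
      pos <- if (m > 0) sort(sample.int(len, m)) else integer(0)
      loci_list[[c]] <- data.frame(
        chrom = rep(names(chromosome_lengths)[c], m),
        pos = pos, stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, loci_list)
    rownames(loci) <- NULL
    m_total <- nrow(loci)
    alleles <- matrix(0L, nrow = n, ncol = m_total)
    if (m_total > 0) {
      dac <- sample(counts_allowed, m_total, replace = TRUE, prob = w)
      for (j in seq_len(m_total))
        alleles[sample.int(n, dac[j]), j] <- 1L
    }
    structure(list(alleles = alleles, loci = loci,
                   chrom_len = chromosome_lengths),
              class = "haplotype_pool")
  })
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool> ", nrow(x$alleles), " haplotypes, ",
      ncol(x$alleles), " loci on ", length(x$chrom_len),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Derived-allele frequencies of a pool
#' @param pool a `haplotype_pool`.
#' @return numeric vector of per-locus derived-allele frequencies.
#' @export
pool_frequencies <- function(pool) {
  if (ncol(pool$alleles) == 0) return(numeric(0))
  colMeans(pool$alleles)
}

#' Build a window-based recombination map
#'
#' Tiles each chromosome with contiguous half-open windows
#' `[start, end)` of `window_size` bp (the last window is truncated to
#' the chromosome end) and assigns each a rate in cM/Mb. With
#' `halve = TRUE` all genetic lengths are multiplied by 0.5, the usual
#' convention when simulating hermaphrodites for species where one sex
#' does not recombine (as in *Drosophila* males).
#'
#' @param chromosome_lengths named numeric vector of chromosome lengths
#'   (bp).
#' @param window_size window width in bp (default 100 kb).
#' @param rates either a single rate in cM/Mb applied to every window,
#'   or a numeric vector with one rate per window (concatenated over
#'   chromosomes in order).
#' @param halve multiply all genetic lengths by 0.5.
#' @return An object of class `recomb_map`: a data.frame with columns
#'   `chrom`, `start`, `end` (1-based, half-open) and `rate_cM_per_Mb`,
#'   with attributes `halve` and `chrom_len`.
#' @export
generate_recomb_map <- function(chromosome_lengths, window_size = 1e5,
                                rates = 2, halve = TRUE) {
  if (window_size <= 0) stop("window_size must be positive")
  if (any(rates < 0)) stop("recombination rates must be >= 0")
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  rows <- vector("list", length(chromosome_lengths))
  for (c in seq_along(chromosome_lengths)) {
    len <- chromosome_lengths[c]
    starts <- seq(1, len, by = window_size)
    ends <- pmin(starts + window_size, len + 1)
    rows[[c]] <- data.frame(chrom = names(chromosome_lengths)[c],
                            start = starts, end = ends,
                            stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  if (length(rates) == 1) {
    map$rate_cM_per_Mb <- rates
  } else {
    if (length(rates) != nrow(map))
      stop("need one rate per window (", nrow(map), "), got ", length(rates))
    map$rate_cM_per_Mb <- rates
  }
  rownames(map) <- NULL
  structure(map, halve = halve, chrom_len = chromosome_lengths,
            class = c("recomb_map", "data.frame"))
}

#' Per-window and total genetic lengths of a map
#'
#' @param map a `recomb_map`.
#' @return numeric vector of window genetic lengths in Morgans (after
#'   halving if the map's `halve` flag is set); the total per chromosome
#'   is available via `tapply(window_morgans(map), map$chrom, sum)`.
#' @export
window_morgans <- function(map) {
  scale <- if (isTRUE(attr(map, "halve"))) 0.5 else 1
  map$rate_cM_per_Mb / 100 / 1e6 * (map$end - map$start) * scale
}

# Precompute per-locus genetic coordinates used by the gamete kernel.
# Returns chrom_start (0-based C indexing, with sentinel), gpos (Morgans
# within chromosome) and glen (Morgans per chromosome). Loci must be
# grouped by chromosome with strictly increasing positions.
map_index <- function(loci, map) {
  chroms <- unique(loci$chrom)
  if (any(rle(as.character(loci$chrom))$values != chroms))
    stop("loci must be grouped by chromosome")
  scale <- if (isTRUE(attr(map, "halve"))) 0.5 else 1
  n_loci <- nrow(loci)
  gpos <- numeric(n_loci)
  glen <- numeric(length(chroms))
  chrom_start <- integer(length(chroms) + 1)
  for (ci in seq_along(chroms)) {
    w <- map[map$chrom == chroms[ci], , drop = FALSE]
    if (nrow(w) == 0) stop("chromosome ", chroms[ci], " not in map")
    w <- w[order(w$start), , drop = FALSE]
    mpb <- w$rate_cM_per_Mb / 100 / 1e6 * scale    # Morgans per bp
    wlen <- mpb * (w$end - w$start)
    cum <- c(0, cumsum(wlen))
    glen[ci] <- cum[length(cum)]
    sel <- which(loci$chrom == chroms[ci])
    chrom_start[ci] <- sel[1] - 1L
    pos <- loci$pos[sel]
    if (any(diff(pos) <= 0))
      stop("positions must be strictly increasing within a chromosome")
    wi <- findInterval(pos, w$start)
    if (any(wi == 0) || any(pos >= w$end[pmin(wi, nrow(w))]))
      stop("locus outside recombination map on chromosome ", chroms[ci])
    gpos[sel] <- cum[wi] + (pos - w$start[wi]) * mpb[wi]
  }
  chrom_start[length(chroms) + 1] <- n_loci
  list(chrom_start = chrom_start, gpos = gpos, glen = glen,
       chroms = chroms)
}

#' Flag loci in low-recombination windows
#'
#' Low-recombination regions inflate the false-positive rate of
#' detection scans because hitchhiking extends over large distances;
#' this returns a logical mask that evaluation steps can use to exclude
#' such loci.
#'
#' @param pool a `haplotype_pool`.
#' @param map a `recomb_map` covering the pool's loci.
#' @param min_rate windows with rate (cM/Mb) strictly below this are
#'   flagged.
#' @return logical vector, `TRUE` for loci to exclude.
#' @export
flag_low_recomb <- function(pool, map, min_rate) {
  out <- logical(nrow(pool$loci))
  for (ci in unique(pool$loci$chrom)) {
    w <- map[map$chrom == ci, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    sel <- which(pool$loci$chrom == ci)
    wi <- findInterval(pool$loci$pos[sel], w$start)
    out[sel] <- w$rate_cM_per_Mb[wi] < min_rate
  }
  out
}

#' Write / read a haplotype pool as plain text
#'
#' Format (`erpool v1`): two header lines, then one line per locus with
#' chromosome, position and one `0`/`1` character per haplotype:
#' \preformatted{
#' #erpool v1
#' #chrom_lengths chr1=100000;chr2=50000
#' chr1<TAB>123<TAB>0100110...
#' }
#'
#' @param pool a `haplotype_pool`.
#' @param path file path.
#' @return `write_pool` returns `path` invisibly; `read_pool` returns a
#'   `haplotype_pool`. The round trip is lossless.
#' @export
write_pool <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#erpool v1", con)
  writeLines(paste0("#chrom_lengths ",
                    paste0(names(pool$chrom_len), "=",
                           format(pool$chrom_len, scientific = FALSE,
                                  trim = TRUE),
                           collapse = ";")), con)
  if (nrow(pool$loci) > 0) {
    halls <- apply(pool$alleles, 2, paste, collapse = "")
    writeLines(paste(pool$loci$chrom, pool$loci$pos, halls, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != "#erpool v1")
    stop("not an erpool v1 file: ", path)
  if (!startsWith(lines[2], "#chrom_lengths "))
    stop("line 2: missing #chrom_lengths header")
  spec <- strsplit(sub("^#chrom_lengths ", "", lines[2]), ";")[[1]]
  kv <- strsplit(spec, "=")
  chrom_len <- vapply(kv, function(x) as.numeric(x[2]), 0)
  names(chrom_len) <- vapply(kv, `[`, "", 1)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(structure(list(
      alleles = matrix(0L, 0, 0),
      loci = data.frame(chrom = character(0), pos = integer(0)),
      chrom_len = chrom_len), class = "haplotype_pool"))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_hap <- NULL
  loci <- data.frame(chrom = character(length(body)),
                     pos = integer(length(body)))
  cols <- vector("list", length(body))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 3)
      stop("line ", i + 2, ": expected 3 tab-separated fields, got ",
           length(p))
    loci$chrom[i] <- p[1]
    pos <- suppressWarnings(as.integer(p[2]))
    if (is.na(pos)) stop("line ", i + 2, ": malformed position '", p[2], "'")
    loci$pos[i] <- pos
    ch <- strsplit(p[3], "")[[1]]
    bad <- which(!ch %in% c("0", "1"))
    if (length(bad))
      stop("line ", i + 2, ", haplotype ", bad[1],
           ": non-binary allele code '", ch[bad[1]], "'")
    if (is.null(n_hap)) n_hap <- length(ch)
    else if (length(ch) != n_hap)
      stop("line ", i + 2, ": expected ", n_hap, " allele codes, got ",
           length(ch))
    cols[[i]] <- as.integer(ch)
  }
  alleles <- do.call(cbind, cols)
  structure(list(alleles = alleles, loci = loci, chrom_len = chrom_len),
            class = "haplotype_pool")
}

#' Write / read a recombination map as TSV
#'
#' Columns: `chrom`, `window_start`, `window_end` (1-based, half-open),
#' `rate_cM_per_Mb`; a comment header records the format version and the
#' halving flag.
#'
#' @param map a `recomb_map`.
#' @param path file path.
#' @export
write_recomb_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#ermap v1 halve=", attr(map, "halve")), con)
  writeLines(paste0("#chrom_lengths ",
                    paste0(names(attr(map, "chrom_len")), "=",
                           format(attr(map, "chrom_len"),
                                  scientific = FALSE, trim = TRUE),
                           collapse = ";")), con)
  writeLines("chrom\twindow_start\twindow_end\trate_cM_per_Mb", con)
  writeLines(paste(map$chrom, map$start, map$end, map$rate_cM_per_Mb,
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#ermap v1")) stop("not an ermap v1 file")
  halve <- grepl("halve=TRUE", lines[1], fixed = TRUE)
  spec <- strsplit(sub("^#chrom_lengths ", "", lines[2]), ";")[[1]]
  kv <- strsplit(spec, "=")
  chrom_len <- vapply(kv, function(x) as.numeric(x[2]), 0)
  names(chrom_len) <- vapply(kv, `[`, "", 1)
  df <- read.table(text = lines[-(1:3)], sep = "\t",
                   col.names = c("chrom", "start", "end", "rate_cM_per_Mb"),
                   stringsAsFactors = FALSE)
  structure(df, halve = halve, chrom_len = chrom_len,
            class = c("recomb_map", "data.frame"))
}
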