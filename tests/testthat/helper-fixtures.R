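# Small fixtures shared across tests; everything is generated in code.

# a compact two-chromosome pool + uniform map + architecture
tiny_world <- function(n_hap = 200, n_loci = c(150, 150),
                       chrom_len = c(chr1 = 1e6, chr2 = 1e6),
                       rate = 5, n_qtn = 20, h2 = 1, seed = 42) {
  pool <- generate_founders(n_hap, n_loci, chrom_len, maf_min = 0.05,
                            seed = seed)
  map <- generate_recomb_map(chrom_len, 1e5, rate, halve = TRUE)
  arch <- draw_architecture(pool, n_qtn, effect_gamma(0.42, 1),
                            h2 = h2, seed = seed + 1)
  list(pool = pool, map = map, arch = arch)
}

# build a 2 x 2 x k array from base/evolved major-minor count vectors
make_tables <- function(base_major, base_minor, ev_major, ev_minor) {
  k <- length(ev_major)
  arr <- array(0, c(2, 2, k))
  arr[1, 1, ] <- base_major; arr[1, 2, ] <- base_minor
  arr[2, 1, ] <- ev_major;   arr[2, 2, ] <- ev_minor
  arr
}
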