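# Shared simulated fixtures, built once per test run.

# Small end-to-end fixture: 8 contigs over 300 kbp, scaled-down windows.
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 3e5, n_contigs = 8,
                        gap_range = c(0, 2000), min_contig_length = 25000,
                        molecule_length_mean = 20000,
                        molecules_per_barcode = 5, n_barcodes = 200,
                        read_pairs_per_molecule_per_kbp = 1, seed = 11)
      sim <- simulate_dataset(cfg)
      rc <- run_config(k = 31, e = 5000, j = 0.55, c = 3, z = 500,
                       m = c(2, 10000), r = 0.05, a = 0.5, D = TRUE, B = 5)
      cache <<- list(cfg = cfg, sim = sim, rc = rc)
    }
    cache
  }
})

# Tiny mapping fixture: a handful of random contigs plus an index.
map_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(31)
      contigs <- data.frame(
        id = sprintf("c%d", 1:6),
        seq = vapply(1:6, function(i) random_dna(4000), character(1)),
        stringsAsFactors = FALSE)
      contigs$length <- nchar(contigs$seq)
      idx <- build_index(contigs, k = 25, e = 1000, z = 0)
      cache <<- list(contigs = contigs, index = idx, k = 25, e = 1000)
    }
    cache
  }
})
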