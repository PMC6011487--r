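# Independent reference implementations used as test oracles. These
# deliberately avoid the package's C++ code paths.

# Canonical kmers via plain R string ops + Biostrings reverse complement.
oracle_kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  st <- seq_len(n - k + 1L)
  w <- substring(seq, st, st + k - 1L)
  w <- w[!grepl("[^ACGT]", w)]
  if (!length(w)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(w)))
  ifelse(w <= rc, w, rc)
}

# Brute-force best-end mapping over the literal kmer sets of every contig
# end (same discard rule for cross-end ambiguous kmers, no index involved).
oracle_end_sets <- function(end_seqs, k) {
  sets <- lapply(end_seqs, function(s) unique(oracle_kmerize(s, k)))
  tab <- table(unlist(sets))
  multi <- names(tab[tab > 1L])
  lapply(sets, setdiff, y = multi)
}

oracle_map_read <- function(read, end_sets, k, j_min) {
  rk <- unique(oracle_kmerize(read, k))
  if (!length(rk)) return(NA_integer_)
  hits <- vapply(end_sets, function(s) length(intersect(rk, s)), integer(1))
  best <- max(hits)
  if (best == 0L) return(NA_integer_)
  if (sum(hits == best) > 1L) return(NA_integer_)   # ambiguous tie
  if (best / length(rk) < j_min) return(NA_integer_)
  which.max(hits)
}

# Exact two-sided binomial p-value at p0 = 0.5 by full pmf enumeration,
# using the same relative tolerance convention as stats::binom.test.
oracle_binom_p <- function(x, n) {
  d <- choose(n, 0:n)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)]) / 2^n
}

# Minimal barcode_map stand-in for tally/distance unit tests.
make_bmap <- function(barcode, contig_id, which, n = 1L) {
  assoc <- data.frame(barcode = barcode, contig_id = contig_id,
                      which = which, n = as.integer(n),
                      stringsAsFactors = FALSE)
  assoc$end_id <- paste0(assoc$contig_id, ":", assoc$which)
  structure(list(assoc = assoc,
                 ends = unique(assoc[, c("contig_id", "which", "end_id")]),
                 stats = list()),
            class = "barcode_map")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
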