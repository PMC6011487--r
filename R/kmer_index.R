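#' Canonical kmers of a sequence
#'
#' Slides a window of length `k` over the sequence and emits, per window,
#' the lexicographically smaller of the window and its reverse complement
#' (the canonical form), so that matching is strand-independent. Windows
#' containing non-ACGT characters are skipped. Sequences shorter than `k`
#' yield an empty vector.
#'
#' @param seq A single DNA string.
#' @param k Kmer length (>= 1).
#' @return Character vector of canonical kmers in window order (duplicates
#'   retained).
#' @export
kmerize <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1)
  cpp_kmerize(seq, as.integer(k))
}

#' Build the kmer index of contig end regions
#'
#' Shreds the head and tail end regions of each contig into canonical kmers
#' and loads them into a hash table mapping each kmer to its contig end.
#' Kmers occurring in more than one contig end are discarded from the table
#' (recorded as multimapped) so that every retained kmer identifies a unique
#' end; repeats *within* a single end are kept. Contigs shorter than `z` bp
#' are excluded from indexing (they are carried through to output
#' unscaffolded), as are degenerate contigs shorter than 2 bp.
#'
#' @param contigs Assembly `data.frame` from [read_assembly()].
#' @param k Kmer length.
#' @param e End-region length in bp (default 30000).
#' @param z Minimum contig length for graph participation (default 3000).
#' @return A `kmer_index` object: list with `k`, `e`, `z`, `ends` (table of
#'   indexed contig ends with 0-based half-open coordinates), `stats`
#'   (counts of indexed ends and stored/dropped kmers) and the internal
#'   hash-table handle.
#' @export
build_index <- function(contigs, k, e = 30000L, z = 3000L) {
  stopifnot(k >= 1, e > 0, z >= 0)
  keep <- contigs$length >= z & contigs$length >= 2L
  if (!any(keep)) {
    warning("no contig passes the minimum length filter (z = ", z, ")")
  }
  idx <- which(keep)
  ends <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ci <- idx[i]
    ec <- contig_end_coords(contigs$length[ci], e)
    ec$contig_id <- contigs$id[ci]
    ends[[i]] <- ec
  }
  ends <- if (length(ends)) do.call(rbind, ends) else
    data.frame(which = character(), start = integer(), stop = integer(),
               contig_id = character(), stringsAsFactors = FALSE)
  ends <- ends[, c("contig_id", "which", "start", "stop")]
  ends$end_id <- if (nrow(ends)) paste0(ends$contig_id, ":", ends$which)
                 else character(0)
  rownames(ends) <- NULL

  seqs <- contigs$seq[match(ends$contig_id, contigs$id)]
  end_seqs <- substring(seqs, ends$start + 1L, ends$stop)
  ptr <- cpp_build_index(end_seqs, as.integer(k))
  st <- cpp_index_stats(ptr)
  obj <- list(
    k = as.integer(k), e = as.integer(e), z = as.integer(z),
    ends = ends,
    ptr = ptr,
    stats = list(
      n_ends_indexed = nrow(ends),
      n_kmers_stored = st$n_kmers_stored,
      n_kmers_dropped_multimapped = st$n_kmers_dropped_multimapped,
      n_kmers_dropped_nonACGT = st$n_kmers_dropped_nonACGT
    )
  )
  class(obj) <- "kmer_index"
  obj
}

#' Query an index for canonical kmers
#'
#' @param index A `kmer_index`.
#' @param kmers Character vector of canonical kmers (as produced by
#'   [kmerize()]).
#' @return Character vector: the owning `end_id` for uniquely indexed kmers,
#'   `"multimapped"` for kmers discarded for cross-end ambiguity, `NA` for
#'   kmers absent from the indexed regions.
#' @export
index_lookup <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  v <- cpp_index_lookup(index$ptr, kmers)
  out <- rep(NA_character_, length(v))
  out[!is.na(v) & v > 0] <- index$ends$end_id[v[!is.na(v) & v > 0]]
  out[!is.na(v) & v < 0] <- "multimapped"
  out
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer index: k=", x$k, ", e=", x$e, ", z=", x$z, "\n", sep = "")
  cat("  contig ends indexed:", x$stats$n_ends_indexed, "\n")
  cat("  kmers stored:", format(x$stats$n_kmers_stored, big.mark = ","),
      "\n")
  cat("  dropped (multimapped):", x$stats$n_kmers_dropped_multimapped, "\n")
  cat("  dropped (non-ACGT windows):", x$stats$n_kmers_dropped_nonACGT,
      "\n")
  invisible(x)
}

#' Write index statistics to TSV
#'
#' @param index A `kmer_index`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_index_stats <- function(index, path) {
  st <- index$stats
  df <- data.frame(stat = names(st), value = unlist(st, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
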