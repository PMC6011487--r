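#' Mapping filter parameters
#'
#' @param j_min Minimum fraction of a read's kmers that must match a contig
#'   end for the end to be a mapping candidate (default 0.55).
#' @param c_min Minimum mapped read pairs supporting a (barcode, contig end)
#'   association for it to be retained (default 5).
#' @param m_lo,m_hi Allowed range of barcode multiplicity, i.e. total read
#'   pairs carrying the barcode in the whole dataset (default 50--6000).
#'   Barcodes outside the range are dropped entirely.
#' @return A `mapping_params` list.
#' @export
mapping_params <- function(j_min = 0.55, c_min = 5L, m_lo = 50L,
                           m_hi = 6000L) {
  stopifnot(j_min >= 0, j_min <= 1, c_min >= 1, m_lo <= m_hi)
  structure(list(j_min = j_min, c_min = as.integer(c_min),
                 m_lo = as.integer(m_lo), m_hi = as.integer(m_hi)),
            class = "mapping_params")
}

#' Score a read against one contig end
#'
#' Returns the fraction of the read's distinct valid canonical kmers that
#' are uniquely indexed to the given contig end. The denominator counts all
#' distinct valid read kmers, including those the index discarded as
#' multimapped; the numerator counts only kmers attributable to `end_id`.
#' A read yielding no kmers scores 0.
#'
#' @param read A single DNA string.
#' @param end_id Contig end identifier, e.g. `"ctg1:H"`.
#' @param index A `kmer_index`.
#' @return Score in `[0, 1]`.
#' @export
score_read <- function(read, end_id, index) {
  stopifnot(inherits(index, "kmer_index"))
  h <- cpp_read_hits(index$ptr, read)
  if (h$denom == 0L) return(0)
  ei <- match(end_id, index$ends$end_id)
  if (is.na(ei)) stop("unknown contig end: ", end_id)
  hit <- h$hits[h$end == ei]
  if (!length(hit)) return(0)
  hit / h$denom
}

#' Map a read to its best-matching contig end
#'
#' Candidate ends are those hit by at least one of the read's kmers; the
#' best candidate must reach a score of at least `j_min` and be the unique
#' maximum -- score ties are discarded as ambiguous.
#'
#' @param read A single DNA string.
#' @param index A `kmer_index`.
#' @param j_min Minimum score (default 0.55).
#' @return The winning `end_id`, or `NA` if no candidate qualifies.
#' @export
map_read <- function(read, index, j_min = 0.55) {
  stopifnot(inherits(index, "kmer_index"))
  v <- cpp_map_reads(index$ptr, read, j_min)
  ifelse(is.na(v), NA_character_, index$ends$end_id[v])
}

#' Map a read pair, requiring both mates to agree
#'
#' Each mate is mapped independently; the pair maps only when both mates
#' resolve to the same contig end.
#'
#' @param read1,read2 The two mate sequences.
#' @param index A `kmer_index`.
#' @param j_min Minimum score (default 0.55).
#' @return The common `end_id`, or `NA`.
#' @export
map_read_pair <- function(read1, read2, index, j_min = 0.55) {
  e1 <- map_read(read1, index, j_min)
  e2 <- map_read(read2, index, j_min)
  ifelse(!is.na(e1) & !is.na(e2) & e1 == e2, e1, NA_character_)
}

#' Build the barcode-to-contig-end association table
#'
#' The central hash table of the algorithm: for every barcode, the contig
#' ends its read pairs map to, with supporting pair counts. Barcode
#' multiplicity (total read pairs per barcode over the whole dataset,
#' mapped or not) is computed first; pairs whose barcode multiplicity falls
#' outside `[m_lo, m_hi]` are excluded. Each surviving pair whose two mates
#' map to the same contig end increments its (barcode, end) association,
#' and associations supported by fewer than `c_min` pairs are pruned.
#'
#' @param pairs Read pairs from [read_linked_reads()] or the simulator.
#' @param index A `kmer_index`.
#' @param params A [mapping_params()] object.
#' @return A `barcode_map` object: list with `assoc` (data.frame `barcode`,
#'   `end_id`, `contig_id`, `which`, `n`), `multiplicity` (data.frame
#'   `barcode`, `n_pairs`), `ends` (copy of the index end table) and
#'   `stats`, whose categories partition the input pair count.
#' @export
build_barcode_map <- function(pairs, index, params = mapping_params()) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "mapping_params"))
  n_total <- nrow(pairs)
  if (n_total == 0L) warning("empty read stream")
  has_bc <- if (n_total) pairs$has_barcode else logical(0)

  mult_tab <- table(pairs$barcode[has_bc])
  multiplicity <- data.frame(barcode = names(mult_tab),
                             n_pairs = as.integer(mult_tab),
                             stringsAsFactors = FALSE)
  mult_of <- rep(NA_integer_, n_total)
  mult_of[has_bc] <- as.integer(mult_tab[pairs$barcode[has_bc]])
  pass_m <- has_bc & mult_of >= params$m_lo & mult_of <= params$m_hi

  e1 <- rep(NA_integer_, n_total)
  e2 <- rep(NA_integer_, n_total)
  if (any(pass_m)) {
    e1[pass_m] <- cpp_map_reads(index$ptr, pairs$read1[pass_m], params$j_min)
    e2[pass_m] <- cpp_map_reads(index$ptr, pairs$read2[pass_m], params$j_min)
  }
  unmapped <- pass_m & (is.na(e1) | is.na(e2))
  discord <- pass_m & !is.na(e1) & !is.na(e2) & e1 != e2
  concord <- pass_m & !is.na(e1) & !is.na(e2) & e1 == e2

  if (any(concord)) {
    dt <- data.table::data.table(barcode = pairs$barcode[concord],
                                 end = e1[concord])
    assoc <- as.data.frame(dt[, .N, by = list(barcode, end)])
    names(assoc)[3] <- "n"
    pruned <- assoc$n < params$c_min
    n_pruned_pairs <- sum(assoc$n[pruned])
    assoc <- assoc[!pruned, , drop = FALSE]
  } else {
    assoc <- data.frame(barcode = character(), end = integer(),
                        n = integer(), stringsAsFactors = FALSE)
    n_pruned_pairs <- 0L
  }
  assoc$end_id <- index$ends$end_id[assoc$end]
  assoc$contig_id <- index$ends$contig_id[assoc$end]
  assoc$which <- index$ends$which[assoc$end]
  assoc <- assoc[order(assoc$barcode, assoc$end_id),
                 c("barcode", "end_id", "contig_id", "which", "n")]
  rownames(assoc) <- NULL

  stats <- list(
    n_pairs_total = n_total,
    n_pairs_no_barcode = sum(!has_bc),
    n_pairs_multiplicity_filtered = sum(has_bc & !pass_m),
    n_pairs_unmapped = sum(unmapped),
    n_pairs_discordant = sum(discord),
    n_pairs_pruned_low_count = as.integer(n_pruned_pairs),
    n_pairs_stored = sum(assoc$n)
  )
  structure(list(assoc = assoc, multiplicity = multiplicity,
                 ends = index$ends, params = params, stats = stats),
            class = "barcode_map")
}

#' @export
print.barcode_map <- function(x, ...) {
  cat("barcode map:", length(unique(x$assoc$barcode)), "barcodes,",
      nrow(x$assoc), "barcode/contig-end associations\n")
  st <- x$stats
  cat("  pairs total:", st$n_pairs_total,
      "| stored:", st$n_pairs_stored,
      "| no barcode:", st$n_pairs_no_barcode,
      "| multiplicity-filtered:", st$n_pairs_multiplicity_filtered, "\n")
  cat("  unmapped:", st$n_pairs_unmapped,
      "| discordant:", st$n_pairs_discordant,
      "| pruned (< c):", st$n_pairs_pruned_low_count, "\n")
  invisible(x)
}

#' Write the barcode map to TSV
#'
#' @param bmap A `barcode_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_barcode_map <- function(bmap, path) {
  utils::write.table(bmap$assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Barcode sets of every contig end
#'
#' Collects, per contig end, the set of barcodes associated with it after
#' all mapping filters; these are the sets entering the Jaccard index.
#'
#' @param bmap A `barcode_map`.
#' @return Named list: `end_id` -> character vector of barcodes.
#' @export
end_barcode_sets <- function(bmap) {
  stopifnot(inherits(bmap, "barcode_map"))
  split(bmap$assoc$barcode, bmap$assoc$end_id)
}
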