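#' Read a draft assembly from FASTA
#'
#' Loads a draft genome assembly (contigs and/or scaffolds, inclusively
#' called contigs throughout this package). Sequence identifiers are the
#' first whitespace-delimited token of each header; sequences are
#' uppercased. Gzip-compressed files are handled transparently.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return A `data.frame` with columns `id`, `seq` and `length`, one row per
#'   record, in file order.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("assembly file not found: ", path)
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate contig id(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  }
  data.frame(id = ids,
             seq = toupper(as.character(ss)),
             length = Biostrings::width(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write contigs or scaffolds to FASTA
#'
#' @param contigs A `data.frame` with columns `id` and `seq` (a `desc`
#'   column, when present, is appended to the header after a space).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(contigs$seq)
  nm <- contigs$id
  if (!is.null(contigs$desc)) {
    has <- !is.na(contigs$desc) & nzchar(contigs$desc)
    nm[has] <- paste(nm[has], contigs$desc[has])
  }
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Head and tail end regions of a contig
#'
#' Computes the coordinates of the 5' (head) and 3' (tail) end regions used
#' as mapping targets; the contig interior is masked. For contigs of length
#' at least `2e` the regions are exactly `e` bp; shorter contigs are split
#' at the midpoint into non-overlapping halves so that a barcode spanning
#' the whole contig still discriminates the two ends. Contigs shorter than
#' 2 bp cannot form two non-empty ends and yield `NULL`.
#'
#' @param length Contig length in bp.
#' @param e End-region length in bp (default 30000).
#' @return A `data.frame` with rows `head` and `tail` and columns `which`,
#'   `start`, `stop` (0-based, half-open), or `NULL` for degenerate contigs.
#' @export
contig_end_coords <- function(length, e = 30000L) {
  stopifnot(e > 0)
  if (length < 2L) return(NULL)
  if (length >= 2L * e) {
    head_stop <- e
    tail_start <- length - e
  } else {
    head_stop <- length %/% 2L
    tail_start <- head_stop
  }
  data.frame(which = c("H", "T"),
             start = as.integer(c(0L, tail_start)),
             stop  = as.integer(c(head_stop, length)),
             stringsAsFactors = FALSE)
}

# Extract the BX:Z:<value> token from a FASTQ header comment, wherever it
# sits among the whitespace-separated fields. Returns NA when absent.
extract_bx <- function(headers) {
  m <- regmatches(headers, regexpr("BX:Z:\\S+", headers))
  out <- rep(NA_character_, length(headers))
  hit <- grepl("BX:Z:\\S+", headers)
  out[hit] <- sub("^BX:Z:", "", m)
  out
}

#' Read barcoded linked reads from FASTQ
#'
#' Accepts either a single interleaved FASTQ file or a pair of
#' mate-separated files. The molecule barcode is taken from a `BX:Z:` tag
#' anywhere in the header comment (Long Ranger convention); pairs without a
#' tag are kept with `has_barcode = FALSE` and ignored by downstream
#' filters. Gzip input is handled transparently. No barcode whitelist
#' correction is attempted.
#'
#' @param paths Character vector of one (interleaved) or two (paired) FASTQ
#'   paths.
#' @return A `data.frame` with columns `id`, `read1`, `read2`, `barcode`,
#'   `has_barcode`, in file order.
#' @export
read_linked_reads <- function(paths) {
  stopifnot(length(paths) %in% c(1L, 2L))
  for (p in paths) if (!file.exists(p)) stop("FASTQ file not found: ", p)
  if (length(paths) == 1L) {
    ss <- Biostrings::readDNAStringSet(paths, format = "fastq")
    n <- length(ss)
    if (n %% 2L != 0L)
      stop("interleaved FASTQ '", paths, "' has an odd number of records (",
           n, ")")
    i1 <- seq(1L, n, by = 2L)
    h1 <- names(ss)[i1]
    h2 <- names(ss)[i1 + 1L]
    r1 <- toupper(as.character(ss[i1]))
    r2 <- toupper(as.character(ss[i1 + 1L]))
  } else {
    s1 <- Biostrings::readDNAStringSet(paths[1], format = "fastq")
    s2 <- Biostrings::readDNAStringSet(paths[2], format = "fastq")
    if (length(s1) != length(s2))
      stop("paired FASTQ files differ in record count: ",
           length(s1), " vs ", length(s2))
    h1 <- names(s1)
    h2 <- names(s2)
    id1 <- sub("/[12]$", "", sub("\\s.*$", "", h1))
    id2 <- sub("/[12]$", "", sub("\\s.*$", "", h2))
    bad <- which(id1 != id2)
    if (length(bad))
      stop("mismatched read ids between paired files at record ", bad[1],
           ": '", id1[bad[1]], "' vs '", id2[bad[1]], "'")
    r1 <- toupper(as.character(s1))
    r2 <- toupper(as.character(s2))
  }
  if (length(r1) == 0L)
    return(data.frame(id = character(), read1 = character(),
                      read2 = character(), barcode = character(),
                      has_barcode = logical(), stringsAsFactors = FALSE))
  bx <- extract_bx(h1)
  bx2 <- extract_bx(h2)
  use2 <- is.na(bx) & !is.na(bx2)
  bx[use2] <- bx2[use2]
  data.frame(id = sub("/[12]$", "", sub("\\s.*$", "", h1)),
             read1 = r1, read2 = r2,
             barcode = ifelse(is.na(bx), "", bx),
             has_barcode = !is.na(bx),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write linked read pairs to an interleaved FASTQ file
#'
#' Headers carry the barcode as a `BX:Z:` tag, mirroring Long Ranger output.
#'
#' @param pairs A `data.frame` with columns `id`, `read1`, `read2`,
#'   `barcode`, `has_barcode`.
#' @param path Output path; `.gz` triggers compression.
#' @return `path`, invisibly.
#' @export
write_linked_reads <- function(pairs, path) {
  n <- nrow(pairs)
  seqs <- character(2L * n)
  nms <- character(2L * n)
  seqs[seq(1L, by = 2L, length.out = n)] <- pairs$read1
  seqs[seq(2L, by = 2L, length.out = n)] <- pairs$read2
  hdr <- ifelse(pairs$has_barcode,
                paste0(pairs$id, " BX:Z:", pairs$barcode),
                pairs$id)
  nms[seq(1L, by = 2L, length.out = n)] <- hdr
  nms[seq(2L, by = 2L, length.out = n)] <- hdr
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- nms
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
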