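#' Jaccard index of two barcode sets
#'
#' `|x intersect y| / |x union y|`, with the empty-vs-empty case defined as
#' 0 (maximal dissimilarity) so that downstream estimates stay defined.
#'
#' @param x,y Character vectors of barcodes (duplicates ignored).
#' @return Fraction in `[0, 1]`.
#' @export
jaccard_index <- function(x, y) {
  x <- unique(x)
  y <- unique(y)
  u <- length(union(x, y))
  if (u == 0L) return(0)
  length(intersect(x, y)) / u
}

#' Train the empirical Jaccard-to-distance model
#'
#' Contig pairs that are further apart share fewer barcodes, but the shape
#' of that decay depends on sequencing coverage and molecule lengths, so it
#' is learned from the assembly itself: for every contig longer than twice
#' the end-region length, the known distance between its own head and tail
#' regions (`length - 2e`) is recorded together with the Jaccard index of
#' the two regions' barcode sets. Contigs whose ends lack barcode
#' associations contribute a sample with Jaccard 0.
#'
#' @param contigs Assembly `data.frame`.
#' @param bmap A `barcode_map`.
#' @param e End-region length in bp used to build the index.
#' @param B Number of nearest training samples used per estimate
#'   (default 20; capped at the sample count).
#' @return A `distance_model`: list with `samples` (data.frame `contig_id`,
#'   `jaccard`, `distance`, in input contig order) and `B`.
#' @export
train_distance_model <- function(contigs, bmap, e, B = 20L) {
  stopifnot(e > 0, B >= 1, inherits(bmap, "barcode_map"))
  sets <- end_barcode_sets(bmap)
  elig <- which(contigs$length > 2L * e)
  if (!length(elig))
    warning("no contig longer than 2e = ", 2L * e,
            " bp; distance model is empty and estimates will be NA")
  samples <- data.frame(
    contig_id = contigs$id[elig],
    jaccard = vapply(elig, function(i) {
      h <- sets[[paste0(contigs$id[i], ":H")]]
      t <- sets[[paste0(contigs$id[i], ":T")]]
      jaccard_index(if (is.null(h)) character(0) else h,
                    if (is.null(t)) character(0) else t)
    }, numeric(1)),
    distance = contigs$length[elig] - 2L * e,
    stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  structure(list(samples = samples, B = as.integer(B)),
            class = "distance_model")
}

# Median over integers: even count -> mean of the two central values,
# rounded half-up to an integer number of bp.
median_bp <- function(d) {
  d <- sort(d)
  n <- length(d)
  if (n %% 2L == 1L) return(as.integer(d[(n + 1L) / 2L]))
  as.integer(floor((d[n / 2L] + d[n / 2L + 1L]) / 2 + 0.5))
}

#' Estimate the gap between two contig ends
#'
#' Computes the Jaccard index of the two barcode sets and returns the
#' median distance of the `B` training samples with the closest Jaccard
#' indices (ties broken by training order; even counts take the rounded
#' mean of the central pair).
#'
#' @param x,y Character vectors of barcodes for the two linked contig ends.
#' @param model A `distance_model` from [train_distance_model()].
#' @return Estimated distance in bp (integer), or `NA` for an empty model.
#' @export
estimate_gap <- function(x, y, model) {
  stopifnot(inherits(model, "distance_model"))
  estimate_gap_from_jaccard(jaccard_index(x, y), model)
}

#' Estimate a gap size from a precomputed Jaccard index
#'
#' @param q Jaccard index in `[0, 1]`.
#' @param model A `distance_model`.
#' @return Estimated distance in bp (integer), or `NA` for an empty model.
#' @export
estimate_gap_from_jaccard <- function(q, model) {
  stopifnot(inherits(model, "distance_model"))
  s <- model$samples
  if (nrow(s) == 0L) return(NA_integer_)
  o <- order(abs(q - s$jaccard))  # stable: insertion order breaks ties
  sel <- s$distance[o[seq_len(min(model$B, nrow(s)))]]
  median_bp(sel)
}

#' @export
print.distance_model <- function(x, ...) {
  cat("distance model:", nrow(x$samples), "intra-contig samples, B =",
      x$B, "\n")
  if (nrow(x$samples)) {
    cat("  distance range:", min(x$samples$distance), "-",
        max(x$samples$distance), "bp\n")
    cat("  jaccard range:", format(min(x$samples$jaccard), digits = 3),
        "-", format(max(x$samples$jaccard), digits = 3), "\n")
  }
  invisible(x)
}

#' Write the training scatter to TSV
#'
#' One row per intra-contig training sample (Jaccard index vs known
#' distance), suitable for a diagnostic scatter plot of the empirical
#' decay.
#'
#' @param model A `distance_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_samples <- function(model, path) {
  utils::write.table(model$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
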