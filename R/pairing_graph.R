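ORIENTATIONS <- c("HH", "HT", "TH", "TT")

#' Scaffold-graph edge parameters
#'
#' @param l_min Minimum shared-barcode count for an edge; the winning
#'   orientation's count must be strictly greater (default 0).
#' @param r_alpha Significance threshold for the orientation binomial test
#'   (default 0.05).
#' @return A `graph_params` list.
#' @export
graph_params <- function(l_min = 0L, r_alpha = 0.05) {
  stopifnot(l_min >= 0, r_alpha > 0, r_alpha < 1)
  structure(list(l_min = as.integer(l_min), r_alpha = r_alpha),
            class = "graph_params")
}

#' Tally shared barcodes per candidate contig pair and orientation
#'
#' Iterates over the barcode-to-contig-end map: for each pair of distinct
#' contigs sharing a barcode, the orientation cell (HH/HT/TH/TT) implied by
#' the barcode's supported end of each contig is incremented by one. Each
#' barcode contributes at most 1 to a contig pair (set semantics), so the
#' cells of a pair sum to the number of barcodes shared by the two contigs.
#' When a barcode is associated with both ends of one contig (a molecule
#' spanning the whole contig), the end with the larger mapped read-pair
#' count carries its orientation evidence; equal counts are uninformative
#' and that (barcode, contig) is skipped. A barcode associated only with
#' both ends of the same contig produces no pair. Pair keys carry the
#' lexicographically smaller contig id first.
#'
#' @param bmap A `barcode_map`.
#' @return A `pair_tally` data.frame with columns `contigA`, `contigB`,
#'   `HH`, `HT`, `TH`, `TT`, sorted by contig ids.
#' @export
tally_pairs <- function(bmap) {
  stopifnot(inherits(bmap, "barcode_map"))
  empty <- data.frame(contigA = character(), contigB = character(),
                      HH = integer(), HT = integer(), TH = integer(),
                      TT = integer(), stringsAsFactors = FALSE)
  a <- bmap$assoc
  if (nrow(a) == 0L) return(structure(empty, class = c("pair_tally",
                                                       "data.frame")))
  dt <- data.table::as.data.table(a[, c("barcode", "contig_id", "which",
                                        "n")])
  # orientation evidence per (barcode, contig): the better-supported end
  dt <- dt[, list(which = which[which.max(n)], nH = sum(n[which == "H"]),
                  nT = sum(n[which == "T"])),
           by = list(barcode, contig_id)]
  dt <- dt[dt$nH != dt$nT | dt$nH == 0 | dt$nT == 0, ]
  dt <- dt[, c("barcode", "contig_id", "which")]
  m <- merge(dt, dt, by = "barcode", allow.cartesian = TRUE,
             suffixes = c(".a", ".b"))
  m <- m[m$contig_id.a < m$contig_id.b, ]
  if (nrow(m) == 0L) return(structure(empty, class = c("pair_tally",
                                                       "data.frame")))
  m$cell <- paste0(m$which.a, m$which.b)
  cnt <- m[, .N, by = list(contigA = contig_id.a, contigB = contig_id.b,
                           cell)]
  wide <- data.table::dcast(cnt, contigA + contigB ~ cell,
                            value.var = "N", fill = 0L)
  for (o in ORIENTATIONS) if (is.null(wide[[o]])) wide[[o]] <- 0L
  out <- as.data.frame(wide)[, c("contigA", "contigB", ORIENTATIONS)]
  out <- out[order(out$contigA, out$contigB), ]
  rownames(out) <- NULL
  structure(out, class = c("pair_tally", "data.frame"))
}

#' Exact binomial test for contig-pair orientation
#'
#' Tests the null hypothesis that the two orientations with the highest
#' shared-barcode counts are equally likely, using the exact two-sided
#' binomial test with success probability 0.5. The test arbitrates only
#' between competing orientations: when exactly one orientation has support
#' the pair is accepted outright, annotated with the degenerate p-value of
#' `c1` successes in `c1` trials for a uniform output schema. With two or
#' more supported orientations the top one is accepted iff `p < r_alpha`;
#' ties for the top count can never reject the null and the pair is
#' dropped.
#'
#' @param counts Integer vector of 4 shared-barcode counts, in the order
#'   HH, HT, TH, TT.
#' @param r_alpha Significance threshold (default 0.05).
#' @return List with `accepted` (logical), `orientation` (`"HH"`/`"HT"`/
#'   `"TH"`/`"TT"` or `NA`), `p_value`, and `n_shared` (the winning count).
#' @export
binomial_orientation_test <- function(counts, r_alpha = 0.05) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  counts <- as.integer(counts)
  if (all(counts == 0L))
    return(list(accepted = FALSE, orientation = NA_character_,
                p_value = NA_real_, n_shared = 0L))
  o <- order(counts, decreasing = TRUE)  # stable: earlier cell wins ties
  c1 <- counts[o[1]]
  c2 <- counts[o[2]]
  p <- stats::binom.test(c1, c1 + c2, p = 0.5)$p.value
  accepted <- if (sum(counts > 0L) == 1L) TRUE else (c1 > c2) && (p < r_alpha)
  list(accepted = accepted,
       orientation = if (accepted) ORIENTATIONS[o[1]] else NA_character_,
       p_value = p, n_shared = c1)
}

#' Emit scaffold-graph edges from a pair tally
#'
#' Applies the orientation binomial test to every candidate contig pair and
#' outputs an edge for each accepted pair whose winning shared-barcode
#' count strictly exceeds `l_min`. When a trained [distance model]
#' [train_distance_model()] is supplied, each edge is annotated with a gap
#' size estimated from the Jaccard index of the two linked ends' barcode
#' sets.
#'
#' @param tally A `pair_tally` from [tally_pairs()].
#' @param params A [graph_params()] object.
#' @param model Optional `distance_model` for gap estimation.
#' @param bmap The `barcode_map` (required when `model` is given).
#' @return A `data.frame` of edges: `contigA`, `contigB`, `orientation`,
#'   `shared_barcodes`, `p_value`, `est_distance` (`NA` without a model),
#'   sorted by contig ids.
#' @export
emit_edges <- function(tally, params = graph_params(), model = NULL,
                       bmap = NULL) {
  stopifnot(inherits(tally, "pair_tally"), inherits(params, "graph_params"))
  if (!is.null(model) && is.null(bmap))
    stop("a barcode_map is required for distance estimation")
  sets <- if (!is.null(model)) end_barcode_sets(bmap) else NULL
  rows <- vector("list", nrow(tally))
  n_out <- 0L
  for (i in seq_len(nrow(tally))) {
    cnts <- as.integer(tally[i, ORIENTATIONS])
    res <- binomial_orientation_test(cnts, params$r_alpha)
    if (!res$accepted || res$n_shared <= params$l_min) next
    est <- NA_integer_
    if (!is.null(model) && nrow(model$samples) > 0L) {
      ori <- strsplit(res$orientation, "")[[1]]
      xa <- sets[[paste0(tally$contigA[i], ":", ori[1])]]
      yb <- sets[[paste0(tally$contigB[i], ":", ori[2])]]
      est <- estimate_gap(if (is.null(xa)) character(0) else xa,
                          if (is.null(yb)) character(0) else yb, model)
    }
    n_out <- n_out + 1L
    rows[[n_out]] <- data.frame(
      contigA = tally$contigA[i], contigB = tally$contigB[i],
      orientation = res$orientation, shared_barcodes = res$n_shared,
      p_value = res$p_value, est_distance = est,
      stringsAsFactors = FALSE)
  }
  if (n_out == 0L)
    return(data.frame(contigA = character(), contigB = character(),
                      orientation = character(), shared_barcodes = integer(),
                      p_value = numeric(), est_distance = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows[seq_len(n_out)])
  out <- out[order(out$contigA, out$contigB), ]
  rownames(out) <- NULL
  out
}

#' Write the scaffold-graph edge table to TSV
#'
#' @param edges Edge `data.frame` from [emit_edges()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
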