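#' Evaluate scaffold layouts against simulation ground truth
#'
#' Compares the joins made by [build_layouts()] with the true contig
#' order/orientation/gap table produced by [fragment_genome()]. A join is a
#' *correct adjacency* when the two contigs are neighbours in the genome;
#' it is *correctly oriented* when, additionally, the layout strands
#' composed with the draft strands reproduce the true relative orientation.
#'
#' @param layouts A `scaffold_layouts` object.
#' @param truth Truth `data.frame` from [fragment_genome()].
#' @return List with counts (`n_true_adjacencies`, `n_joins`,
#'   `n_correct_adjacency`, `n_correct_oriented`), rates
#'   (`adjacency_recall` = distinct true adjacencies joined / true
#'   adjacencies; `oriented_recall` = the same restricted to correctly
#'   oriented joins; `join_precision` = joins correct in both adjacency and
#'   orientation / joins made), and `gap_table` (`data.frame` of
#'   `true_gap`, `est_gap` for correct joins carrying an estimate).
#' @export
evaluate_layouts <- function(layouts, truth) {
  ord <- structure(truth$order, names = truth$id)
  dstrand <- structure(truth$strand, names = truth$id)
  gap_after <- structure(truth$gap_after, names = truth$order)

  n_joins <- 0L
  n_adj <- 0L
  n_ori <- 0L
  true_gap <- integer(0)
  est_gap <- integer(0)
  adj_joined <- logical(nrow(truth) - 1L)     # per true adjacency (order i)
  adj_recovered <- logical(nrow(truth) - 1L)  # joined with correct orientation
  flip <- function(s) ifelse(s == "+", "-", "+")
  for (l in layouts) {
    if (nrow(l) < 2L) next
    for (i in seq_len(nrow(l) - 1L)) {
      x <- l$contig_id[i]
      y <- l$contig_id[i + 1L]
      n_joins <- n_joins + 1L
      # genome orientation implied by layout strand o draft strand
      gx <- if (l$strand[i] == "+") dstrand[x] else flip(dstrand[x])
      gy <- if (l$strand[i + 1L] == "+") dstrand[y] else flip(dstrand[y])
      d <- ord[y] - ord[x]
      if (abs(d) == 1L) {
        n_adj <- n_adj + 1L
        adj_joined[min(ord[x], ord[y])] <- TRUE
        ok <- (d == 1L && gx == "+" && gy == "+") ||
              (d == -1L && gx == "-" && gy == "-")
        if (ok) {
          n_ori <- n_ori + 1L
          adj_recovered[min(ord[x], ord[y])] <- TRUE
          tg <- gap_after[[as.character(min(ord[x], ord[y]))]]
          if (!is.na(l$gap_after[i])) {
            true_gap <- c(true_gap, tg)
            est_gap <- c(est_gap, l$gap_after[i])
          }
        }
      }
    }
  }
  n_true <- nrow(truth) - 1L
  list(n_true_adjacencies = n_true,
       n_joins = n_joins,
       n_correct_adjacency = n_adj,
       n_correct_oriented = n_ori,
       adjacency_recall = sum(adj_joined) / n_true,
       oriented_recall = sum(adj_recovered) / n_true,
       join_precision = if (n_joins > 0) n_ori / n_joins else NA_real_,
       gap_table = data.frame(true_gap = true_gap, est_gap = est_gap))
}
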