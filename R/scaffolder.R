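#' Path-building parameters
#'
#' @param a_max Maximum allowed ratio of second-best to best
#'   shared-barcode count at a contig end for the end to be extended
#'   (default 0.5); smaller is stricter.
#' @param default_gap Gap size in bp written between joined contigs when no
#'   distance estimate is available (default 100).
#' @param min_gap Minimum visible gap in bp, so that every join remains
#'   detectable downstream (default 10).
#' @return A `path_params` list.
#' @export
path_params <- function(a_max = 0.5, default_gap = 100L, min_gap = 10L) {
  stopifnot(a_max > 0, a_max <= 1, default_gap >= 1, min_gap >= 1)
  structure(list(a_max = a_max, default_gap = as.integer(default_gap),
                 min_gap = as.integer(min_gap)), class = "path_params")
}

# Map an edge to its two contig-end identifiers.
edge_endpoints <- function(edges) {
  data.frame(
    endA = paste0(edges$contigA, ":", substr(edges$orientation, 1, 1)),
    endB = paste0(edges$contigB, ":", substr(edges$orientation, 2, 2)),
    stringsAsFactors = FALSE)
}

#' Convert scaffold-graph edges into linear contig layouts
#'
#' A conservative stand-in for a full-featured graph scaffolder: a contig
#' end is extendable only through an edge that is the reciprocal best
#' (highest shared-barcode count) for both of its endpoints and whose
#' runner-up support at either endpoint is at most `a_max` times the best.
#' Chains of such links become multi-contig layouts with orientations
#' propagated from the edge orientations; all remaining contigs become
#' singleton layouts. Cycles are broken at their weakest link.
#'
#' @param edges Edge `data.frame` from [emit_edges()].
#' @param contigs Assembly `data.frame` (defines the set of contigs and the
#'   singleton output order).
#' @param params A [path_params()] object.
#' @return A `scaffold_layouts` list; each element is a `data.frame` with
#'   columns `contig_id`, `strand` (`"+"`/`"-"`), `gap_after` (estimated bp
#'   or `NA`; always `NA` on the last row).
#' @export
build_layouts <- function(edges, contigs, params = path_params()) {
  stopifnot(inherits(params, "path_params"))
  selected <- integer(0)
  if (nrow(edges) > 0L) {
    ep <- edge_endpoints(edges)
    all_ends <- unique(c(ep$endA, ep$endB))
    # per end: order incident edges by support, then p-value, then partner id
    best_of <- list()
    ratio_ok <- list()
    for (end in all_ends) {
      inc <- which(ep$endA == end | ep$endB == end)
      partner <- ifelse(ep$endA[inc] == end, ep$endB[inc], ep$endA[inc])
      o <- inc[order(-edges$shared_barcodes[inc], edges$p_value[inc],
                     partner)]
      best_of[[end]] <- o[1]
      best_n <- edges$shared_barcodes[o[1]]
      second_n <- if (length(o) > 1L) edges$shared_barcodes[o[2]] else 0L
      ratio_ok[[end]] <- (second_n / best_n) <= params$a_max
    }
    for (i in seq_len(nrow(edges))) {
      ea <- ep$endA[i]
      eb <- ep$endB[i]
      if (best_of[[ea]] == i && best_of[[eb]] == i &&
          ratio_ok[[ea]] && ratio_ok[[eb]]) {
        selected <- c(selected, i)
      }
    }
  }

  # link map: end_id -> list(to = end_id, gap, n, edge)
  link <- new.env(parent = emptyenv())
  for (i in selected) {
    ea <- paste0(edges$contigA[i], ":", substr(edges$orientation[i], 1, 1))
    eb <- paste0(edges$contigB[i], ":", substr(edges$orientation[i], 2, 2))
    assign(ea, list(to = eb, gap = edges$est_distance[i],
                    n = edges$shared_barcodes[i], edge = i), envir = link)
    assign(eb, list(to = ea, gap = edges$est_distance[i],
                    n = edges$shared_barcodes[i], edge = i), envir = link)
  }
  get_link <- function(end) if (exists(end, envir = link)) get(end, envir = link) else NULL
  drop_link <- function(i) {
    ea <- paste0(edges$contigA[i], ":", substr(edges$orientation[i], 1, 1))
    eb <- paste0(edges$contigB[i], ":", substr(edges$orientation[i], 2, 2))
    if (exists(ea, envir = link)) rm(list = ea, envir = link)
    if (exists(eb, envir = link)) rm(list = eb, envir = link)
  }

  other_end <- function(end) {
    cid <- sub(":[HT]$", "", end)
    w <- sub("^.*:", "", end)
    paste0(cid, ":", if (w == "H") "T" else "H")
  }

  # discover components contig by contig; break cycles at the weakest link
  visited <- new.env(parent = emptyenv())
  layouts <- list()
  for (cid in sort(contigs$id)) {
    if (exists(cid, envir = visited)) next
    # collect the component reachable from cid
    comp <- character(0)
    comp_edges <- integer(0)
    queue <- cid
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      if (cur %in% comp) next
      comp <- c(comp, cur)
      for (w in c("H", "T")) {
        l <- get_link(paste0(cur, ":", w))
        if (!is.null(l)) {
          comp_edges <- union(comp_edges, l$edge)
          queue <- c(queue, sub(":[HT]$", "", l$to))
        }
      }
    }
    # cycle iff every contig in the component has both ends linked
    is_cycle <- length(comp) > 1L && all(vapply(comp, function(cc) {
      !is.null(get_link(paste0(cc, ":H"))) &&
        !is.null(get_link(paste0(cc, ":T")))
    }, logical(1)))
    if (is_cycle) {
      ce <- comp_edges[order(edges$shared_barcodes[comp_edges],
                             edges$contigA[comp_edges],
                             edges$contigB[comp_edges])]
      drop_link(ce[1])
    }
    # find the terminal contigs (at most one linked end)
    terms <- comp[vapply(comp, function(cc) {
      is.null(get_link(paste0(cc, ":H"))) ||
        is.null(get_link(paste0(cc, ":T")))
    }, logical(1))]
    start <- sort(terms)[1]
    # starting strand: the linked end must face forward
    if (!is.null(get_link(paste0(start, ":T")))) {
      strand <- "+"
    } else if (!is.null(get_link(paste0(start, ":H")))) {
      strand <- "-"
    } else {
      strand <- "+"  # singleton
    }
    ids <- character(0)
    strands <- character(0)
    gaps <- integer(0)
    cur <- start
    repeat {
      assign(cur, TRUE, envir = visited)
      ids <- c(ids, cur)
      strands <- c(strands, strand)
      fwd <- paste0(cur, ":", if (strand == "+") "T" else "H")
      l <- get_link(fwd)
      if (is.null(l)) {
        gaps <- c(gaps, NA_integer_)
        break
      }
      gaps <- c(gaps, if (is.na(l$gap)) NA_integer_ else as.integer(l$gap))
      nxt <- sub(":[HT]$", "", l$to)
      strand <- if (sub("^.*:", "", l$to) == "H") "+" else "-"
      cur <- nxt
    }
    gaps[length(gaps)] <- NA_integer_
    layouts[[length(layouts) + 1L]] <-
      data.frame(contig_id = ids, strand = strands, gap_after = gaps,
                 stringsAsFactors = FALSE)
  }
  structure(layouts, class = "scaffold_layouts", edges_used = selected)
}

#' Flatten layouts into a table
#'
#' @param layouts A `scaffold_layouts` object.
#' @return A `data.frame` with columns `scaffold_id`, `position`,
#'   `contig_id`, `strand`, `gap_after`.
#' @export
layout_table <- function(layouts) {
  rows <- lapply(seq_along(layouts), function(i) {
    l <- layouts[[i]]
    data.frame(scaffold_id = sprintf("scaffold_%04d", i),
               position = seq_len(nrow(l)),
               contig_id = l$contig_id, strand = l$strand,
               gap_after = l$gap_after, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge layouts into scaffold sequences
#'
#' Concatenates oriented contig sequences (minus strand contigs are
#' reverse-complemented), separating joined contigs by runs of `N`: the
#' estimated gap size when present (floored at `min_gap` so the join stays
#' visible), else `default_gap`. Every input contig appears exactly once;
#' singleton layouts are emitted unchanged under their original id, merged
#' scaffolds are named `scaffold_<i>` with their constituents listed in the
#' header description.
#'
#' @param layouts A `scaffold_layouts` object.
#' @param contigs Assembly `data.frame`.
#' @param path Optional FASTA output path.
#' @param params A [path_params()] object (gap defaults).
#' @return Invisibly, a `data.frame` of scaffolds (`id`, `seq`, `desc`);
#'   written to `path` when given.
#' @export
write_scaffolds <- function(layouts, contigs, path = NULL,
                            params = path_params()) {
  seq_of <- structure(contigs$seq, names = contigs$id)
  ids <- character(length(layouts))
  seqs <- character(length(layouts))
  descs <- character(length(layouts))
  n_merged <- 0L
  for (i in seq_along(layouts)) {
    l <- layouts[[i]]
    pieces <- ifelse(l$strand == "+", seq_of[l$contig_id],
                     revcomp(seq_of[l$contig_id]))
    if (nrow(l) == 1L) {
      ids[i] <- l$contig_id
      seqs[i] <- pieces
      descs[i] <- ""
    } else {
      gapn <- ifelse(is.na(l$gap_after[-nrow(l)]), params$default_gap,
                     pmax(l$gap_after[-nrow(l)], params$min_gap))
      parts <- character(2L * nrow(l) - 1L)
      parts[seq(1L, by = 2L, length.out = nrow(l))] <- pieces
      parts[seq(2L, by = 2L, length.out = nrow(l) - 1L)] <-
        strrep("N", gapn)
      n_merged <- n_merged + 1L
      ids[i] <- sprintf("scaffold_%04d", n_merged)
      seqs[i] <- paste(parts, collapse = "")
      descs[i] <- paste0(l$contig_id, l$strand, collapse = ",")
    }
  }
  out <- data.frame(id = ids, seq = seqs, desc = descs,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) write_assembly(out, path)
  invisible(out)
}
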