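#' Run configuration for the scaffolding pipeline
#'
#' Bundles every tunable parameter under its conventional single-letter
#' flag name. Defaults target high-coverage Chromium data on a contiguous
#' human-scale draft; desk-scale runs on synthetic data typically scale
#' down `k`, `e` and `z`.
#'
#' @param k Kmer length.
#' @param e Contig end-region length in bp (default 30000).
#' @param j Minimum fraction of read kmers matching a contig end
#'   (default 0.55).
#' @param c Minimum read pairs per barcode/contig-end association
#'   (default 5).
#' @param l Minimum shared-barcode count for an edge, strict (default 0).
#' @param r Significance threshold of the orientation test (default 0.05).
#' @param z Minimum contig length to participate in the graph
#'   (default 3000).
#' @param m Length-2 vector, allowed barcode multiplicity range
#'   (default `c(50, 6000)`).
#' @param B Training samples per gap estimate (default 20).
#' @param a Ambiguity ratio for path extension (default 0.5).
#' @param D Logical: estimate gap distances (default `FALSE`).
#' @param t Thread count; accepted for interface compatibility, the
#'   current implementation is sequential and results are identical for
#'   any value (default 1).
#' @param default_gap Gap written when no estimate is available
#'   (default 100).
#' @return A `run_config` list.
#' @export
run_config <- function(k = 60L, e = 30000L, j = 0.55, c = 5L, l = 0L,
                       r = 0.05, z = 3000L, m = c(50L, 6000L), B = 20L,
                       a = 0.5, D = FALSE, t = 1L, default_gap = 100L) {
  stopifnot(k >= 1, e > 0, j >= 0, j <= 1, c >= 1, l >= 0, r > 0, r < 1,
            z >= 0, length(m) == 2L, m[1] <= m[2], B >= 1, a > 0, a <= 1,
            t >= 1)
  structure(list(k = as.integer(k), e = as.integer(e), j = j,
                 c = as.integer(c), l = as.integer(l), r = r,
                 z = as.integer(z), m = as.integer(m), B = as.integer(B),
                 a = a, D = isTRUE(D), t = as.integer(t),
                 default_gap = as.integer(default_gap)),
            class = "run_config")
}

#' Run the full scaffolding pipeline
#'
#' Index -> map -> tally -> orientation test -> (optional) gap estimation
#' -> path layout -> scaffold FASTA. Inputs may be file paths or the
#' in-memory objects produced by [read_assembly()], [read_linked_reads()]
#' or the simulator. The run is fully deterministic: identical inputs and
#' configuration give byte-identical outputs regardless of `t`.
#'
#' @param draft Path to the draft FASTA, or an assembly `data.frame`.
#' @param reads Path(s) to barcoded FASTQ (interleaved or paired), or a
#'   read-pair `data.frame`.
#' @param outdir Optional output directory; when given, writes
#'   `edges.tsv`, `scaffolds.fa`, `layouts.tsv`, `stats.tsv` and (with
#'   `D = TRUE`) `distance_samples.tsv`.
#' @param config A [run_config()] object.
#' @return Invisibly, a list with `contigs`, `index`, `bmap`, `tally`,
#'   `model` (or `NULL`), `edges`, `layouts`, `scaffolds`, `stats` and the
#'   echoed `config`.
#' @export
run_pipeline <- function(draft, reads, outdir = NULL,
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  contigs <- if (is.character(draft)) read_assembly(draft) else draft
  pairs <- if (is.character(reads)) read_linked_reads(reads) else reads

  index <- build_index(contigs, k = config$k, e = config$e, z = config$z)
  mp <- mapping_params(j_min = config$j, c_min = config$c,
                       m_lo = config$m[1], m_hi = config$m[2])
  bmap <- build_barcode_map(pairs, index, mp)
  tally <- tally_pairs(bmap)
  model <- if (config$D)
    train_distance_model(contigs, bmap, e = config$e, B = config$B)
  else NULL
  gp <- graph_params(l_min = config$l, r_alpha = config$r)
  edges <- emit_edges(tally, gp, model = model, bmap = bmap)
  pp <- path_params(a_max = config$a, default_gap = config$default_gap)
  layouts <- build_layouts(edges, contigs, pp)
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scaffolds <- write_scaffolds(layouts, contigs,
                               path = if (!is.null(outdir))
                                 file.path(outdir, "scaffolds.fa"),
                               params = pp)

  stats <- c(index$stats, bmap$stats,
             list(n_candidate_pairs = nrow(tally),
                  n_edges = nrow(edges),
                  n_joins = sum(vapply(layouts, nrow, integer(1)) - 1L),
                  n_scaffolds = length(layouts)))

  if (!is.null(outdir)) {
    write_edges(edges, file.path(outdir, "edges.tsv"))
    utils::write.table(layout_table(layouts),
                       file.path(outdir, "layouts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(model))
      write_distance_samples(model, file.path(outdir,
                                              "distance_samples.tsv"))
    cfg_echo <- vapply(config, function(v) paste(v, collapse = "-"),
                       character(1))
    st <- data.frame(
      stat = c(paste0("param_", names(cfg_echo)), names(stats)),
      value = c(unname(cfg_echo),
                vapply(stats, function(v) as.character(v), character(1))),
      stringsAsFactors = FALSE)
    utils::write.table(st, file.path(outdir, "stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(contigs = contigs, index = index, bmap = bmap,
                 tally = tally, model = model, edges = edges,
                 layouts = layouts, scaffolds = scaffolds, stats = stats,
                 config = config))
}
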