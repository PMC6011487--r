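#' Simulation configuration
#'
#' Defaults describe a desk-scale Chromium-like linked-read experiment over
#' a 2 Mbp genome: a draft of 40 contigs separated by small gaps, long DNA
#' molecules with exponentially distributed lengths (mean 50 kbp), 10
#' molecules pooled per barcode (barcode reuse, the estimator's main
#' confounder, is therefore modelled), and read pairs drawn from each
#' molecule at a rate giving ~0.2x per-molecule coverage -- the
#' low-per-molecule / high-genome-wide coverage regime characteristic of
#' the platform. With 400 barcodes the genome-wide molecule coverage is
#' ~100x (matching published linked-read simulation profiles) and the
#' read coverage roughly 20x. Reads are error-free by default because downstream
#' mapping is by exact kmer match; an error rate can be set to stress that
#' assumption.
#'
#' @param genome_length Genome size in bp.
#' @param n_contigs Number of draft contigs.
#' @param gap_range Length-2 vector, uniform range of inter-contig gaps
#'   (bp).
#' @param min_contig_length Minimum draft contig length (bp).
#' @param molecule_length_mean Mean molecule length (bp); lengths are
#'   exponential (set `molecule_length_dist = "lognormal"` for a lognormal
#'   with the same mean and sdlog 0.5).
#' @param molecules_per_barcode Molecules pooled per barcode.
#' @param n_barcodes Number of barcodes.
#' @param read_length Read length (bp).
#' @param read_pairs_per_molecule_per_kbp Read-pair sampling rate per kbp
#'   of molecule.
#' @param insert_mean,insert_sd Fragment (insert) size distribution.
#' @param error_rate Per-base substitution rate (default 0).
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 2e6,
                       n_contigs = 40L,
                       gap_range = c(0L, 5000L),
                       min_contig_length = 40000L,
                       molecule_length_mean = 50000,
                       molecules_per_barcode = 10L,
                       n_barcodes = 400L,
                       read_length = 150L,
                       read_pairs_per_molecule_per_kbp = 2 / 3,
                       insert_mean = 400,
                       insert_sd = 50,
                       error_rate = 0,
                       molecule_length_dist = c("exponential", "lognormal"),
                       seed = 1L) {
  molecule_length_dist <- match.arg(molecule_length_dist)
  stopifnot(genome_length > 0, n_contigs >= 2, gap_range[1] <= gap_range[2],
            gap_range[1] >= 0, min_contig_length >= 2,
            molecule_length_mean > 0, molecules_per_barcode >= 1,
            n_barcodes >= 1, read_length >= 1,
            read_pairs_per_molecule_per_kbp > 0,
            insert_mean >= 2 * read_length, error_rate >= 0, error_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a random genome
#'
#' Uniform random ACGT sequence; optionally a tandem duplication is planted
#' for repeat stress tests.
#'
#' @param config A [sim_config()].
#' @param tandem_dup Optional length-2 vector `c(start, length)`: copy the
#'   `length` bp at `start` and insert them immediately after themselves
#'   (total genome length grows by `length`).
#' @return A single DNA string.
#' @export
simulate_genome <- function(config, tandem_dup = NULL) {
  stopifnot(inherits(config, "sim_config"), config$genome_length >= 1)
  set.seed(config$seed)
  g <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                    replace = TRUE), collapse = "")
  if (!is.null(tandem_dup)) {
    s <- tandem_dup[1]
    len <- tandem_dup[2]
    unit <- substr(g, s, s + len - 1L)
    g <- paste0(substr(g, 1L, s + len - 1L), unit,
                substr(g, s + len, nchar(g)))
  }
  g
}

#' Fragment a genome into a shuffled, randomly oriented draft assembly
#'
#' Cuts the genome into `n_contigs` segments separated by gaps drawn
#' uniformly from `gap_range` (gap bases are removed from the draft and
#' recorded in the truth table), then shuffles contig order and flips
#' random contigs to the minus strand, as a draft assembler would present
#' them. Contig lengths are a uniform partition of the remaining bases with
#' a floor of `min_contig_length`, giving the broad length spread typical
#' of draft assemblies.
#'
#' @param genome DNA string from [simulate_genome()].
#' @param config A [sim_config()].
#' @return List with `contigs` (draft `data.frame`: `id`, `seq`, `length`)
#'   and `truth` (`data.frame` in genome order: `order`, `id`,
#'   `genome_start` (1-based), `length`, `strand` of the draft sequence
#'   relative to the genome, `gap_after` in bp, `NA` on the last contig).
#' @export
fragment_genome <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  G <- nchar(genome)
  n <- config$n_contigs
  gaps <- round(runif(n - 1L, config$gap_range[1], config$gap_range[2]))
  total_contig <- G - sum(gaps)
  slack <- total_contig - n * config$min_contig_length
  if (slack < 0)
    stop("infeasible: ", n, " contigs of >= ", config$min_contig_length,
         " bp plus gaps exceed the genome length")
  cuts <- sort(runif(n - 1L, 0, slack))
  parts <- diff(c(0, cuts, slack))
  lens <- config$min_contig_length + floor(parts)
  rem <- total_contig - sum(lens)
  if (rem > 0) lens[seq_len(rem)] <- lens[seq_len(rem)] + 1L
  starts <- cumsum(c(1, lens[-n] + gaps))
  seqs <- substring(genome, starts, starts + lens - 1L)

  ord <- sample.int(n)             # draft presentation order
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ids <- character(n)
  ids[ord] <- sprintf("ctg%03d", seq_len(n))  # id assigned by draft order
  draft_seqs <- ifelse(strands == "+", seqs, revcomp(seqs))
  contigs <- data.frame(id = ids[ord], seq = draft_seqs[ord],
                        length = lens[ord], stringsAsFactors = FALSE)
  truth <- data.frame(order = seq_len(n), id = ids,
                      genome_start = as.integer(starts),
                      length = as.integer(lens), strand = strands,
                      gap_after = c(as.integer(gaps), NA_integer_),
                      stringsAsFactors = FALSE)
  list(contigs = contigs, truth = truth)
}

#' Simulate Chromium-like barcoded linked reads
#'
#' For each barcode, `molecules_per_barcode` long molecules are placed
#' uniformly on the genome with exponential (or lognormal) lengths; read
#' pairs are drawn from each molecule at the configured rate, keeping
#' per-molecule coverage well below 1x. Each pair is a forward window and
#' the reverse complement of a downstream window separated by a sampled
#' insert size; sequences are exact genome substrings unless `error_rate`
#' is set. Every read header carries its barcode as a `BX:Z:` tag when
#' written with [write_linked_reads()].
#'
#' @param genome DNA string.
#' @param config A [sim_config()].
#' @return List with `pairs` (`data.frame`: `id`, `read1`, `read2`,
#'   `barcode`, `has_barcode`, plus truth columns `molecule`, `pos1`,
#'   `pos2` giving 1-based genome coordinates of the two windows) and
#'   `molecules` (`data.frame`: `molecule`, `barcode`, `start`, `end`).
#' @export
simulate_linked_reads <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  G <- nchar(genome)
  nb <- config$n_barcodes
  barcodes <- make_barcodes(nb)
  M <- nb * config$molecules_per_barcode
  mol_bc <- rep(barcodes, each = config$molecules_per_barcode)
  mol_start <- sample.int(G, M, replace = TRUE)
  mol_len <- if (config$molecule_length_dist == "exponential") {
    pmax(1, round(rexp(M, 1 / config$molecule_length_mean)))
  } else {
    sdlog <- 0.5
    ml <- log(config$molecule_length_mean) - sdlog^2 / 2
    pmax(1, round(stats::rlnorm(M, ml, sdlog)))
  }
  mol_end <- pmin(mol_start + mol_len - 1L, G)
  mol_len <- mol_end - mol_start + 1L
  n_pairs <- rpois(M, config$read_pairs_per_molecule_per_kbp *
                        mol_len / 1000)

  mi <- rep.int(seq_len(M), n_pairs)
  np <- length(mi)
  inserts <- pmax(2L * config$read_length,
                  round(rnorm(np, config$insert_mean, config$insert_sd)))
  fits <- inserts <= mol_len[mi]
  mi <- mi[fits]
  inserts <- inserts[fits]
  np <- length(mi)
  p1 <- mol_start[mi] +
    floor(runif(np) * (mol_len[mi] - inserts + 1L))
  p2 <- p1 + inserts - config$read_length
  r1 <- substring(genome, p1, p1 + config$read_length - 1L)
  r2 <- revcomp(substring(genome, p2, p2 + config$read_length - 1L))
  if (config$error_rate > 0) {
    r1 <- mutate_reads(r1, config$error_rate)
    r2 <- mutate_reads(r2, config$error_rate)
  }
  pairs <- data.frame(id = sprintf("sim%07d", seq_len(np)),
                      read1 = r1, read2 = r2,
                      barcode = mol_bc[mi], has_barcode = TRUE,
                      molecule = mi, pos1 = p1, pos2 = p2,
                      stringsAsFactors = FALSE)
  molecules <- data.frame(molecule = seq_len(M), barcode = mol_bc,
                          start = mol_start, end = mol_end,
                          stringsAsFactors = FALSE)
  list(pairs = pairs, molecules = molecules)
}

# Chromium-style barcodes: unique random 16-mers with a "-1" suffix.
make_barcodes <- function(n) {
  bc <- replicate(n, paste(sample(c("A", "C", "G", "T"), 16L,
                                  replace = TRUE), collapse = ""))
  while (anyDuplicated(bc)) {
    d <- which(duplicated(bc))
    bc[d] <- replicate(length(d), paste(sample(c("A", "C", "G", "T"), 16L,
                                               replace = TRUE),
                                        collapse = ""))
  }
  paste0(bc, "-1")
}

# Random substitutions at the given per-base rate.
mutate_reads <- function(reads, rate) {
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(r)
    v <- strsplit(r, "")[[1]]
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs [simulate_genome()], [fragment_genome()] and
#' [simulate_linked_reads()] under one seed, optionally writing the draft
#' FASTA, interleaved FASTQ (with `BX:Z:` tags) and truth TSVs to a
#' directory. Fully deterministic for a fixed config.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `genome`, `contigs`, `truth`, `pairs`, `molecules`
#'   and, when `dir` is given, `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  genome <- simulate_genome(config)
  frag <- fragment_genome(genome, config)
  reads <- simulate_linked_reads(genome, config)
  out <- list(genome = genome, contigs = frag$contigs, truth = frag$truth,
              pairs = reads$pairs, molecules = reads$molecules)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(draft = file.path(dir, "draft.fa"),
                  reads = file.path(dir, "reads.fq.gz"),
                  truth = file.path(dir, "truth_layout.tsv"),
                  read_truth = file.path(dir, "truth_reads.tsv"))
    write_assembly(frag$contigs, paths$draft)
    write_linked_reads(reads$pairs, paths$reads)
    utils::write.table(frag$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      reads$pairs[, c("id", "barcode", "molecule", "pos1", "pos2")],
      paths$read_truth, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}
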