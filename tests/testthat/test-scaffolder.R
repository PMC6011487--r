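mk_edges <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$p_value)) df$p_value <- 1e-4
  if (is.null(df$est_distance)) df$est_distance <- NA_integer_
  df
}

mk_contigs <- function(ids, len = 200) {
  data.frame(id = ids,
             seq = vapply(seq_along(ids), function(i) random_dna(len),
                          character(1)),
             length = len, stringsAsFactors = FALSE)
}

test_that("a sole reciprocal-best link joins two contigs in orientation", {
  set.seed(2)
  ctg <- mk_contigs(c("A", "B"))
  e <- mk_edges(contigA = "A", contigB = "B", orientation = "TH",
                shared_barcodes = 10L)
  lay <- build_layouts(e, ctg)
  joined <- Filter(function(l) nrow(l) > 1, lay)
  expect_length(joined, 1L)
  expect_equal(joined[[1]]$contig_id, c("A", "B"))
  expect_equal(joined[[1]]$strand, c("+", "+"))

  # head-to-head link flips the downstream contig
  e2 <- mk_edges(contigA = "A", contigB = "B", orientation = "HH",
                 shared_barcodes = 10L)
  j2 <- Filter(function(l) nrow(l) > 1, build_layouts(e2, ctg))[[1]]
  expect_equal(j2$contig_id, c("A", "B"))   # A starts; its head faces B
  expect_equal(j2$strand, c("-", "+"))
})

test_that("the ambiguity ratio blocks extension through contested ends", {
  set.seed(3)
  ctg <- mk_contigs(c("A", "B", "C"))
  e <- mk_edges(contigA = c("A", "A"), contigB = c("B", "C"),
                orientation = c("TH", "TH"), shared_barcodes = c(10L, 9L))
  lay <- build_layouts(e, ctg, path_params(a_max = 0.5))
  expect_true(all(vapply(lay, nrow, integer(1)) == 1L))  # 9/10 > 0.5

  lay2 <- build_layouts(e, ctg, path_params(a_max = 0.95))
  expect_equal(max(vapply(lay2, nrow, integer(1))), 2L)  # now extendable
})

test_that("a triangle of equal edges contesting shared ends yields no join", {
  set.seed(8)
  ctg <- mk_contigs(c("A", "B", "C"))
  # every contig end hosts two equally supported edges
  e <- mk_edges(contigA = c("A", "B", "A"), contigB = c("B", "C", "C"),
                orientation = c("TH", "HT", "TT"),
                shared_barcodes = c(5L, 5L, 5L))
  lay <- build_layouts(e, ctg, path_params(a_max = 0.5))
  expect_true(all(vapply(lay, nrow, integer(1)) == 1L))
})

test_that("cycles are broken at the weakest link", {
  set.seed(13)
  ctg <- mk_contigs(c("A", "B", "C"))
  e <- mk_edges(contigA = c("A", "B", "A"), contigB = c("B", "C", "C"),
                orientation = c("TH", "TH", "HT"),   # A+ B+ C+ ... C:T->A:H
                shared_barcodes = c(10L, 9L, 8L))
  lay <- build_layouts(e, ctg, path_params(a_max = 1))
  chain <- Filter(function(l) nrow(l) > 1, lay)
  expect_length(chain, 1L)
  expect_equal(nrow(chain[[1]]), 3L)   # weakest edge (A,C) dropped
  expect_equal(chain[[1]]$contig_id, c("A", "B", "C"))
  expect_equal(chain[[1]]$strand, c("+", "+", "+"))
})

test_that("raising a_max never reduces the number of joins", {
  set.seed(19)
  ids <- sprintf("c%02d", 1:12)
  ctg <- mk_contigs(ids)
  n <- 18
  e <- mk_edges(contigA = sample(ids, n, TRUE),
                contigB = sample(ids, n, TRUE),
                orientation = sample(c("HH", "HT", "TH", "TT"), n, TRUE),
                shared_barcodes = sample(1:20, n, TRUE))
  e <- e[e$contigA < e$contigB, ]
  e <- e[!duplicated(e[, c("contigA", "contigB")]), ]
  joins <- function(a) sum(vapply(build_layouts(e, ctg,
                                                path_params(a_max = a)),
                                  nrow, integer(1)) - 1L)
  js <- vapply(c(0.2, 0.5, 0.8, 1.0), joins, numeric(1))
  expect_true(all(diff(js) >= 0))
})

test_that("scaffold sequences are assembled with oriented contigs and N gaps", {
  set.seed(23)
  ctg <- mk_contigs(c("A", "B"), len = 120)
  lay <- structure(list(data.frame(
    contig_id = c("A", "B"), strand = c("+", "-"),
    gap_after = c(100L, NA), stringsAsFactors = FALSE)),
    class = "scaffold_layouts")
  sc <- write_scaffolds(lay, ctg)
  expect_equal(sc$seq,
               paste0(ctg$seq[1], strrep("N", 100), revcomp(ctg$seq[2])))
  expect_match(sc$desc, "A\\+,B-")

  # tiny estimates floor at the minimum visible gap; NA uses the default
  lay[[1]]$gap_after[1] <- 3L
  expect_match(write_scaffolds(lay, ctg)$seq, "[ACGT]N{10}[ACGT]")
  lay[[1]]$gap_after[1] <- NA
  expect_match(write_scaffolds(lay, ctg)$seq, "[ACGT]N{100}[ACGT]")

  # singleton emitted unchanged under its own id
  single <- structure(list(data.frame(contig_id = "A", strand = "+",
                                      gap_after = NA_integer_,
                                      stringsAsFactors = FALSE)),
                      class = "scaffold_layouts")
  s1 <- write_scaffolds(single, ctg)
  expect_equal(s1$id, "A")
  expect_equal(s1$seq, ctg$seq[1])
})

test_that("every base of every contig is conserved through scaffolding", {
  fx <- small_fixture()
  res <- run_pipeline(fx$sim$contigs, fx$sim$pairs, config = fx$rc)
  sc <- res$scaffolds
  # every contig appears exactly once across layouts
  placed <- unlist(lapply(res$layouts, function(l) l$contig_id))
  expect_setequal(placed, fx$sim$contigs$id)
  expect_equal(anyDuplicated(placed), 0L)
  # scaffold sequences reconstruct exactly from layouts
  seq_of <- structure(fx$sim$contigs$seq, names = fx$sim$contigs$id)
  for (i in seq_along(res$layouts)) {
    l <- res$layouts[[i]]
    parts <- ifelse(l$strand == "+", seq_of[l$contig_id],
                    revcomp(seq_of[l$contig_id]))
    gaps <- ifelse(is.na(l$gap_after), 100L, pmax(l$gap_after, 10L))
    want <- paste0(paste0(parts[-nrow(l)], strrep("N", gaps[-nrow(l)]),
                          collapse = ""), parts[nrow(l)])
    expect_equal(sc$seq[i], want)
  }
  # base content conserved (A/T and C/G symmetric under revcomp)
  base_at <- function(x) sum(nchar(gsub("[^AT]", "", x)))
  base_cg <- function(x) sum(nchar(gsub("[^CG]", "", x)))
  expect_equal(base_at(sc$seq), base_at(fx$sim$contigs$seq))
  expect_equal(base_cg(sc$seq), base_cg(fx$sim$contigs$seq))
})
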