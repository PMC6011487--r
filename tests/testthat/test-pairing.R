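test_that("pair tally implements barcode set semantics over contig pairs", {
  # one barcode linking A-head and B-tail
  t1 <- tally_pairs(make_bmap("b1", c("A", "B"), c("H", "T"), c(5, 5)))
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$HT, 1L)
  expect_equal(t1$HH + t1$TH + t1$TT, 0L)

  # both ends of the same contig: no self pair
  t2 <- tally_pairs(make_bmap("b1", c("A", "A"), c("H", "T"), c(5, 3)))
  expect_equal(nrow(t2), 0L)

  # three contigs: every cross pair incremented once
  t3 <- tally_pairs(make_bmap("b1", c("A", "B", "C"), c("H", "H", "T"),
                              c(4, 4, 4)))
  expect_equal(nrow(t3), 3L)
  expect_equal(t3$HH[t3$contigA == "A" & t3$contigB == "B"], 1L)
  expect_equal(t3$HT[t3$contigA == "A" & t3$contigB == "C"], 1L)
  expect_equal(t3$HT[t3$contigA == "B" & t3$contigB == "C"], 1L)

  # a barcode seen at both ends of B votes with B's better-supported end
  t4 <- tally_pairs(make_bmap("b1", c("A", "B", "B"), c("T", "H", "T"),
                              c(6, 5, 2)))
  expect_equal(t4$TH, 1L)
  expect_equal(t4$HH + t4$HT + t4$TT, 0L)

  # equal support at both ends of B is uninformative: no increment
  t5 <- tally_pairs(make_bmap("b1", c("A", "B", "B"), c("T", "H", "T"),
                              c(6, 4, 4)))
  expect_equal(nrow(t5), 0L)
})

test_that("tally cells sum to the shared-barcode count of the contig pair", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 60
    assoc <- data.frame(
      barcode = sample(sprintf("b%02d", 1:12), n, replace = TRUE),
      contig_id = sample(c("A", "B", "C", "D"), n, replace = TRUE),
      which = sample(c("H", "T"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    assoc$n <- sample(1:9, n, replace = TRUE)
    assoc <- assoc[!duplicated(assoc[, c("barcode", "contig_id", "which")]), ]
    bm <- make_bmap(assoc$barcode, assoc$contig_id, assoc$which, assoc$n)
    tal <- tally_pairs(bm)

    # independent oracle: per barcode/contig resolve the informative end,
    # then intersect barcode sets per contig pair
    votes <- do.call(rbind, lapply(split(assoc, assoc$barcode), function(d) {
      do.call(rbind, lapply(split(d, d$contig_id), function(g) {
        if (nrow(g) == 2L && g$n[1] == g$n[2]) return(NULL)
        g[which.max(g$n), c("barcode", "contig_id", "which")]
      }))
    }))
    ids <- sort(unique(assoc$contig_id))
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      shared <- intersect(votes$barcode[votes$contig_id == ids[i]],
                          votes$barcode[votes$contig_id == ids[j]])
      row <- tal[tal$contigA == ids[i] & tal$contigB == ids[j], ]
      got <- if (nrow(row)) sum(row[, c("HH", "HT", "TH", "TT")]) else 0L
      expect_equal(got, length(shared))
    }
  }
})

test_that("relabeling the two contigs mirrors the tally orientation", {
  bm1 <- make_bmap(c("b1", "b1", "b2", "b2"), c("A", "B", "A", "B"),
                   c("H", "T", "H", "T"), c(3, 3, 2, 2))
  t1 <- tally_pairs(bm1)
  # rename so the former B sorts first
  bm2 <- make_bmap(c("b1", "b1", "b2", "b2"), c("Z", "B", "Z", "B"),
                   c("H", "T", "H", "T"), c(3, 3, 2, 2))
  t2 <- tally_pairs(bm2)
  expect_equal(t1$HT, 2L)   # A:H with B:T
  expect_equal(t2$TH, 2L)   # mirrored: B:T with Z:H
})

test_that("orientation binomial test matches its worked examples", {
  # single supported orientation: accepted, degenerate p annotated
  r <- binomial_orientation_test(c(10, 0, 0, 0))
  expect_true(r$accepted)
  expect_equal(r$orientation, "HH")
  expect_equal(r$p_value, 2 * 0.5^10)

  # perfectly symmetric counts can never reject the null
  r <- binomial_orientation_test(c(5, 5, 0, 0))
  expect_false(r$accepted)
  expect_equal(r$p_value, 1)

  # 7 vs 3: two-sided p = 0.34375, not significant at 0.05
  r <- binomial_orientation_test(c(7, 3, 0, 0))
  expect_false(r$accepted)
  expect_equal(r$p_value, 0.34375)

  # clear winner among four populated cells
  r <- binomial_orientation_test(c(2, 40, 8, 3))
  expect_true(r$accepted)
  expect_equal(r$orientation, "HT")
  expect_equal(r$n_shared, 40L)

  # all-zero input is rejected outright
  expect_false(binomial_orientation_test(c(0, 0, 0, 0))$accepted)
})

test_that("binomial p-values match exact pmf enumeration", {
  for (n in c(1, 2, 7, 10, 17, 30)) {
    for (x in seq(ceiling(n / 2), n)) {
      r <- binomial_orientation_test(c(x, n - x, 0, 0))
      expect_equal(r$p_value, oracle_binom_p(x, n), tolerance = 1e-12)
    }
  }
})

test_that("edges respect the strict shared-barcode threshold and the test", {
  mk_tally <- function(...) {
    df <- data.frame(...)
    structure(df, class = c("pair_tally", "data.frame"))
  }
  # single orientation, one barcode: emitted at l = 0 (strict >)
  t1 <- mk_tally(contigA = "A", contigB = "B", HH = 0L, HT = 1L, TH = 0L,
                 TT = 0L)
  expect_equal(nrow(emit_edges(t1, graph_params(l_min = 0))), 1L)
  expect_equal(nrow(emit_edges(t1, graph_params(l_min = 1))), 0L)

  # winning count must strictly exceed l
  t2 <- mk_tally(contigA = "A", contigB = "B", HH = 10L, HT = 0L, TH = 0L,
                 TT = 0L)
  expect_equal(nrow(emit_edges(t2, graph_params(l_min = 9))), 1L)
  expect_equal(nrow(emit_edges(t2, graph_params(l_min = 10))), 0L)

  # binomial rejection vetoes the edge regardless of counts
  t3 <- mk_tally(contigA = "A", contigB = "B", HH = 50L, HT = 48L, TH = 0L,
                 TT = 0L)
  expect_equal(nrow(emit_edges(t3, graph_params())), 0L)
})

test_that("raising l or lowering r never adds edges", {
  set.seed(33)
  tal <- structure(data.frame(
    contigA = sprintf("a%02d", 1:40), contigB = sprintf("b%02d", 1:40),
    HH = rpois(40, 6), HT = rpois(40, 2), TH = rpois(40, 2),
    TT = rpois(40, 1), stringsAsFactors = FALSE),
    class = c("pair_tally", "data.frame"))
  key <- function(e) paste(e$contigA, e$contigB)
  e_base <- emit_edges(tal, graph_params(l_min = 0, r_alpha = 0.1))
  e_l <- emit_edges(tal, graph_params(l_min = 5, r_alpha = 0.1))
  e_r <- emit_edges(tal, graph_params(l_min = 0, r_alpha = 0.01))
  expect_true(all(key(e_l) %in% key(e_base)))
  expect_true(all(key(e_r) %in% key(e_base)))
})
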