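# Break-end contig calling, truncation and streaming assembly.

sc_read_graph <- function(n_reads, k = 25, seq = NULL, start = 500,
                          aligned = 30, clip = 20) {
  if (is.null(seq)) seq <- random_dna(aligned + clip)
  g <- pg_new(k)
  for (i in seq_len(n_reads)) {
    g <- pg_add_read(g, seq, 30, 60, paste0("sc", i), starts = start,
                     anchored_bases = seq_len(aligned))
  }
  list(g = g, seq = seq)
}

test_that("three identical soft-clipped reads assemble into one contig spelling the clip", {
  set.seed(5)
  fx <- sc_read_graph(3)
  ctg <- pg_call_contigs(fx$g, min_support = 3, read_len = 50)
  expect_equal(nrow(ctg), 1)
  expect_equal(ctg$unanchored_seq, substr(fx$seq, 31, 50))
  expect_setequal(ctg$support[[1]], c("sc1", "sc2", "sc3"))
  # anchored flank retained in the contig sequence
  expect_true(endsWith(fx$seq, ctg$seq) || ctg$seq == fx$seq)
})

test_that("contigs below the minimum support are filtered", {
  set.seed(6)
  fx <- sc_read_graph(2)
  ctg <- pg_call_contigs(fx$g, min_support = 3, read_len = 50)
  expect_equal(nrow(ctg), 0)
})

test_that("after calling, no unanchored k-mer retains support", {
  set.seed(7)
  fx <- sc_read_graph(3)
  g <- fx$g
  ctg <- pg_call_contigs(g, min_support = 3, read_len = 50)
  # replay the removal: all contig reads removed leaves only anchored nodes
  g2 <- pg_remove_reads(g, unlist(ctg$support))
  nd <- pg_nodes(g2)
  expect_true(all(nd$anchored))
})

test_that("a self-intersecting read loops without truncation and k-mer chaining restores it", {
  g <- pg_new(4)
  for (s in 10:14) g <- pg_add_read(g, "TAAAAC", 30, 60, "r1", starts = s)
  loose <- pg_call_contigs(g, min_support = 1, read_len = 6, truncate = FALSE)
  expect_equal(loose$start_pos, 10)
  expect_equal(loose$seq, "TAAAAAAAAC")
  tight <- pg_call_contigs(g, min_support = 1, read_len = 6, truncate = TRUE)
  expect_equal(tight$start_pos, 10)
  expect_equal(tight$seq, "TAAAAC")
})

test_that("truncation leaves read-spelled paths unchanged", {
  # single read path
  g <- pg_new(5)
  g <- pg_add_read(g, "ACGGTTACCGAT", 25, 60, "solo", starts = 100)
  nd <- pg_nodes(g)
  tr <- truncate_contig(nd[, c("pos", "code")], g)
  expect_equal(breakendr:::spell_path(tr$code, 5), "ACGGTTACCGAT")
  # two staggered reads agreeing on all transitions
  g2 <- pg_new(5)
  s <- "ACGGTTACCGATTGCA"
  g2 <- pg_add_read(g2, substr(s, 1, 12), 25, 60, "a", starts = 100)
  g2 <- pg_add_read(g2, substr(s, 5, 16), 25, 60, "b", starts = 104)
  ctg <- pg_call_contigs(g2, min_support = 1, read_len = 10)
  expect_equal(ctg$seq, s)
})

test_that("each read supports at most one emitted contig", {
  set.seed(8)
  g <- pg_new(15)
  # two junction clusters sharing no reads
  for (i in 1:3) g <- pg_add_read(g, random_dna(40), 30, 60,
                                  paste0("a", i), starts = 100)
  for (i in 1:3) g <- pg_add_read(g, random_dna(40), 30, 60,
                                  paste0("b", i), starts = 5000)
  ctg <- pg_call_contigs(g, min_support = 1, read_len = 30)
  ids <- unlist(ctg$support)
  expect_equal(anyDuplicated(ids), 0)
})

test_that("called paths are maximal: exhaustive enumeration finds nothing heavier", {
  set.seed(9)
  for (rep in 1:10) {
    g <- pg_new(6)
    for (i in 1:6) {
      g <- pg_add_read(g, random_dna(12), sample(15:35, 1), 50,
                       paste0("r", i), starts = sample(1:12, 1))
    }
    nd <- pg_nodes(g)
    if (nrow(nd) > 200) next
    ed <- breakendr:::pg_edges(nd, 6)
    oracle <- brute_force_max_path(nd, ed)
    mp <- breakendr:::max_weight_path(nd[, c("pos", "code", "weight")], ed)
    expect_equal(mp$weight, oracle)
  }
})

test_that("streaming assembly equals whole-graph assembly", {
  set.seed(10)
  mk_greads <- function(n, spread) {
    rows <- lapply(seq_len(n), function(i) {
      s <- random_dna(40)
      st <- sample(seq(1, spread), 1)
      tibble::tibble(read_id = paste0("r", i), seq = s,
                     baseq = list(rep(28L, 40)), mapq = 60,
                     start_lo = st, start_hi = st + sample(0:30, 1),
                     anch_lo = NA_real_, anch_hi = NA_real_)
    })
    dplyr::arrange(dplyr::bind_rows(rows), start_lo)
  }
  for (rep in 1:3) {
    gr <- mk_greads(12, spread = 3000)
    a <- assemble_streaming(gr, k = 12, min_support = 1, read_len = 40,
                            streaming = TRUE)
    b <- assemble_streaming(gr, k = 12, min_support = 1, read_len = 40,
                            streaming = FALSE)
    expect_equal(a$seq, b$seq)
    expect_equal(lapply(a$support, sort), lapply(b$support, sort))
  }
  # two junctions far apart equal independent per-region assembly
  g1 <- mk_greads(4, 10); g2 <- mk_greads(4, 10)
  g2 <- dplyr::mutate(g2, start_lo = start_lo + 1e6,
                      start_hi = start_hi + 1e6,
                      read_id = paste0(read_id, "_far"))
  both <- dplyr::bind_rows(g1, g2)
  ab <- assemble_streaming(both, k = 12, min_support = 1, read_len = 40)
  sep <- dplyr::bind_rows(
    assemble_streaming(g1, k = 12, min_support = 1, read_len = 40),
    assemble_streaming(g2, k = 12, min_support = 1, read_len = 40))
  expect_setequal(ab$seq, sep$seq)
})

test_that("out-of-order evidence streams are rejected and empty input is empty", {
  gr <- tibble::tibble(read_id = c("a", "b"), seq = c("ACGTACGTACGT", "ACGTACGTACGT"),
                       baseq = list(rep(28L, 12), rep(28L, 12)), mapq = 60,
                       start_lo = c(100, 50), start_hi = c(100, 50),
                       anch_lo = NA_real_, anch_hi = NA_real_)
  expect_error(assemble_streaming(gr, k = 6), "out of order")
  empty <- gr[0, ]
  expect_equal(nrow(assemble_streaming(empty, k = 6)), 0)
})
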