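# Positional de Bruijn graph structure.

test_that("node adjacency requires adjacent positions and overlapping k-mers", {
  expect_true(edge_exists("ACGT", 5, "CGTA", 6))
  expect_false(edge_exists("ACGT", 5, "CGTA", 7))
  expect_false(edge_exists("ACGT", 5, "GGTA", 6))
  expect_error(edge_exists("ACGT", 5, "CGTAA", 6), "equal length")
})

test_that("k-mer codes round-trip and flag ambiguous bases", {
  s <- "ACGTACGTTGCA"
  for (k in c(4, 7, 11)) {
    codes <- kmer_codes(s, k)
    expect_length(codes, nchar(s) - k + 1)
    expect_equal(kmer_string(codes, k),
                 substring(s, seq_along(codes), seq_along(codes) + k - 1))
  }
  cn <- kmer_codes("ACGNACGT", 4)
  expect_true(all(is.na(cn[1:4])))   # k-mers covering the N
  expect_false(anyNA(cn[5]))
  expect_length(kmer_codes("ACG", 4), 0)
})

test_that("soft-clipped reads are placed as if fully mapped with anchored flags", {
  # 6M4S at position 100, k = 4: anchored k-mers at 100..102, unanchored
  # (clip-crossing) k-mers at 103..106
  g <- pg_new(4)
  g <- pg_add_read(g, "ACGTACGTTG", 30, 60, "r1", starts = 100,
                   anchored_bases = 1:6)
  nd <- pg_nodes(g)
  expect_equal(nd$pos, as.numeric(100:106))
  expect_equal(nd$anchored, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(kmer_string(nd$code[1], 4), "ACGT")
})

test_that("multi-placement reads cover every concordant start and reads shorter than k are skipped", {
  g <- pg_new(5)
  g <- pg_add_read(g, "ACGTACG", 20, 60, "dp1", starts = 50:60)
  nd <- pg_nodes(g)
  # 3 k-mers x 11 starts, brute-force position set
  expected <- sort(unique(as.vector(outer(50:60, 0:2, `+`))))
  expect_setequal(unique(nd$pos), expected)
  expect_true(all(!nd$anchored))
  expect_warning(g2 <- pg_add_read(g, "ACG", 20, 60, "tiny", starts = 1),
                 "shorter than k")
  expect_identical(pg_nodes(g2), nd)
})

test_that("node weight accumulates rounded k-mer weights over support", {
  g <- pg_new(4)
  g <- pg_add_read(g, "ACGTAC", 30, 60, "r1", starts = 10)
  g <- pg_add_read(g, "ACGTAC", 30, 60, "r2", starts = 10)
  nd <- pg_nodes(g)
  w1 <- round(kmer_weight(rep(30, 4), 60))
  expect_equal(nd$weight, rep(2 * w1, 3))
  expect_equal(pg_total_weight(g), 6 * w1)
})

test_that("acyclicity: every edge advances position by exactly one", {
  set.seed(42)
  g <- pg_new(4)
  for (i in 1:20) {
    g <- pg_add_read(g, random_dna(12), 25, 50, paste0("r", i),
                     starts = sample(1:40, 1))
  }
  nd <- pg_nodes(g)
  ed <- breakendr:::pg_edges(nd, 4)
  expect_true(all(nd$pos[ed$to_idx] == nd$pos[ed$from_idx] + 1))
})

test_that("compression merges branchless chains and expansion round-trips", {
  # linear chain of 5 single-support nodes -> one path node of length 5
  g <- pg_new(4)
  g <- pg_add_read(g, "ACGTACGT", 20, 60, "r1", starts = 30)
  pn <- pg_compress(g)
  expect_equal(nrow(pn), 1)
  expect_length(pn$codes[[1]], 5)
  # a fork is not merged across the branch
  g2 <- pg_add_read(g, "ACGTACTT", 20, 60, "r2", starts = 30)
  pn2 <- pg_compress(g2)
  expect_gt(nrow(pn2), 1)
  # random graphs: expand(compress(G)) == G exactly
  set.seed(7)
  for (rep in 1:5) {
    gr <- pg_new(5)
    for (i in 1:8) {
      gr <- pg_add_read(gr, random_dna(14), sample(10:35, 1), 50,
                        paste0("r", i), starts = sample(1:30, 1))
    }
    nd <- pg_nodes(gr)[, c("pos", "code", "weight", "anchored")]
    ex <- pg_expand(pg_compress(gr))
    expect_equal(as.data.frame(ex),
                 as.data.frame(dplyr::arrange(nd, pos, code)))
  }
})

test_that("interval compression collapses identical chains at adjacent starts", {
  g <- pg_new(4)
  for (s in 100:104) g <- pg_add_read(g, "AACCGGT", 20, 60, "dp", starts = s)
  pn <- pg_compress(g)
  # AACCGGT has 4 distinct k-mers: one interval-compressed chain
  expect_equal(nrow(pn), 1)
  expect_equal(pn$start, 100)
  expect_equal(pn$end, 104)
})

test_that("graph text dump round-trips support and weights", {
  g <- pg_new(4)
  g <- pg_add_read(g, "ACGTACGTTG", 28, 55, "readA", starts = 100,
                   anchored_bases = 1:6)
  g <- pg_add_read(g, "CGTACG", 30, 60, "readB", starts = 101)
  path <- withr::local_tempfile(fileext = ".tsv")
  pg_write_tsv(g, path)
  g2 <- pg_read_tsv(path)
  expect_equal(as.data.frame(pg_nodes(g2)), as.data.frame(pg_nodes(g)))
  expect_equal(pg_total_weight(g2), pg_total_weight(g))
})

test_that("read removal deletes exactly that read's support", {
  g <- pg_new(4)
  g <- pg_add_read(g, "ACGTACGT", 20, 60, "keep", starts = 10)
  g <- pg_add_read(g, "ACGTACGT", 20, 60, "drop", starts = 10)
  g2 <- pg_remove_reads(g, "drop")
  expect_setequal(unique(g2$support$read_id), "keep")
  expect_equal(nrow(pg_nodes(g2)), 5)
  expect_equal(pg_total_weight(g2), pg_total_weight(g) / 2)
})
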