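# Contig realignment into breakpoint evidence.

mk_contig <- function(seq, chrom = "chr1", direction = "+", anchor_start,
                      anchor_end, anchor_nodes = 10L) {
  tibble::tibble(contig_id = "ctg_test", chrom = chrom,
                 direction = direction, anchor_start = anchor_start,
                 anchor_end = anchor_end, anchor_nodes = anchor_nodes,
                 seq = seq)
}

fake_m <- structure(list(concordant_hi = 400), class = "sv_metrics")

test_that("a contig that fully matches the reference is discarded", {
  set.seed(50)
  ref <- c(chr1 = random_dna(8000))
  ctg <- mk_contig(substr(ref, 2001, 2060), anchor_start = 2001,
                   anchor_end = 2060)
  bp <- realign_contig(ctg, ref, fake_m)
  expect_equal(nrow(bp), 0)
})

test_that("a two-segment contig yields one breakpoint joining the segments", {
  set.seed(51)
  ref <- c(chr1 = random_dna(8000))
  ctg <- mk_contig(paste0(substr(ref, 1001, 1030), substr(ref, 5001, 5030)),
                   anchor_start = 1001, anchor_end = 1030)
  bp <- realign_contig(ctg, ref, fake_m)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$s_l, 1030)
  expect_equal(bp$dir_l, "+")
  expect_equal(bp$s_h, 5001)
  expect_equal(bp$dir_h, "-")
  expect_equal(bp$untemplated, "")
  expect_equal(bp$origin, "ASSEMBLY")
})

test_that("compound contigs yield a junction chain within the depth limit", {
  set.seed(52)
  ref <- c(chr1 = random_dna(9000))
  # A ++ C ++ B with C a unique 40 bp fragment from a third locus
  ctg <- mk_contig(paste0(substr(ref, 1001, 1040), substr(ref, 4001, 4040),
                          substr(ref, 7001, 7040)),
                   anchor_start = 1001, anchor_end = 1040)
  bp <- realign_contig(ctg, ref, fake_m)
  expect_equal(nrow(bp), 2)
  # junction placement may slide by chance micro-homology at the segment
  # boundaries; accept any diagonally consistent placement near the truth
  match_junction <- function(row, tl, th) {
    d <- tl - row$s_l
    abs(d) <= 2 && row$s_h == th - d
  }
  bp <- dplyr::arrange(bp, s_l)
  expect_true(match_junction(bp[1, ], 1040, 4001))
  expect_true(match_junction(bp[2, ], 4040, 7001))
  # depth bound: many segments truncate at max_depth junctions
  seg <- lapply(seq(1, 8 * 900, by = 900), function(s)
    substr(ref, s, s + 39))
  ctg8 <- mk_contig(paste(unlist(seg), collapse = ""),
                    anchor_start = 1, anchor_end = 40)
  bp8 <- realign_contig(ctg8, ref, fake_m, max_depth = 4)
  expect_lte(nrow(bp8), 4)
})

test_that("untemplated bases between segments are captured", {
  set.seed(53)
  ref <- c(chr1 = random_dna(8000))
  # choose boundary bases that differ from the flanks so the insertion
  # cannot slide into either aligned segment
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  ins <- paste0(other(substr(ref, 1041, 1041)), "ATTACAGATTAC",
                other(substr(ref, 5000, 5000)))
  ctg <- mk_contig(paste0(substr(ref, 1001, 1040), ins,
                          substr(ref, 5001, 5040)),
                   anchor_start = 1001, anchor_end = 1040)
  bp <- realign_contig(ctg, ref, fake_m)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$untemplated, ins)
})

test_that("an inverted junction is reported with matching directions", {
  set.seed(54)
  ref <- c(chr1 = random_dna(8000))
  ctg <- mk_contig(paste0(substr(ref, 1001, 1040),
                          revcomp(substr(ref, 5001, 5040))),
                   anchor_start = 1001, anchor_end = 1040)
  bp <- realign_contig(ctg, ref, fake_m)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$dir_l, "+")
  expect_equal(bp$dir_h, "+")
  expect_equal(bp$s_h, 5040)
})

test_that("an unlocatable residue becomes single-break-end evidence", {
  set.seed(55)
  ref <- c(chr1 = random_dna(6000))
  novel <- random_dna(40)   # not from the reference
  ctg <- mk_contig(paste0(substr(ref, 1001, 1040), novel),
                   anchor_start = 1001, anchor_end = 1040)
  bp <- realign_contig(ctg, ref, fake_m)
  expect_equal(nrow(bp), 1)
  expect_true(is.na(bp$chrom_h))
  expect_equal(bp$s_l, 1040)
})

test_that("query bases are consumed disjointly across a junction chain", {
  set.seed(56)
  ref <- c(chr1 = random_dna(9000))
  ctg <- mk_contig(paste0(substr(ref, 1001, 1040), substr(ref, 4001, 4040),
                          substr(ref, 7001, 7040)),
                   anchor_start = 1001, anchor_end = 1040)
  bp <- realign_contig(ctg, ref, fake_m)
  # each junction consumes a fresh segment: partner loci are all distinct
  expect_equal(anyDuplicated(bp$s_h), 0)
})
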