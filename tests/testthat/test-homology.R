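# Microhomology, inexact homology and untemplated-sequence annotation.

test_that("a junction in unique sequence has zero homology", {
  set.seed(70)
  ref <- c(chr1 = random_dna(5000))
  # force distinct flanks
  h <- junction_homology(ref, "chr1", 1000, "+", "chr1", 3000, "-")
  oracle <- scan_del_homology(ref[["chr1"]], 1000, 3000)
  expect_equal(h$homlen, oracle$homlen)
  expect_equal(h$homseq == "", h$homlen == 0)
})

test_that("planted deletion homology is recovered and matches a direct scan", {
  genome <- sim_genome(20000, seed = 71)
  events <- tibble::tibble(type = "DEL", chrom = "chr1", pos = 8000L,
                           size = 500L, hom_len = 4L)
  pl <- sim_plant_svs(genome, events, seed = 72)
  tr <- pl$truth
  expect_equal(tr$hom_len, 4)
  # independent character-level scan of the adjusted reference
  oracle <- scan_del_homology(pl$reference[["chr1"]], tr$pos_l, tr$pos_h)
  expect_equal(oracle$homlen, 4)
  h <- junction_homology(pl$reference, "chr1", tr$pos_l, "+",
                         "chr1", tr$pos_h, "-")
  expect_equal(h$homlen, 4)
  expect_equal(h$hi - h$lo, 4)           # CIPOS width equals homlen
  expect_equal(nchar(h$homseq), h$homlen)
})

test_that("untemplated insertions resolve the junction: homology zero", {
  set.seed(73)
  ref <- c(chr1 = random_dna(5000))
  h <- junction_homology(ref, "chr1", 1000, "+", "chr1", 3000, "-",
                         untemplated = "GATTACA")
  expect_equal(h$homlen, 0)
})

test_that("inexact homology always contains the exact interval", {
  set.seed(74)
  ref <- c(chr1 = random_dna(20000))
  for (i in 1:20) {
    p1 <- sample(500:9000, 1); p2 <- p1 + sample(500:9000, 1)
    dl <- sample(c("+", "-"), 1); dh <- sample(c("+", "-"), 1)
    h <- junction_homology(ref, "chr1", p1, dl, "chr1", p2, dh)
    expect_gte(h$ileft, h$left)
    expect_gte(h$iright, h$right)
  }
})

test_that("inversion junctions compare reverse-complement flanks", {
  set.seed(75)
  base <- random_dna(5000)
  # make ref[2001..2006] the reverse complement of ref[3995..4000] so a
  # (+,+) junction at 2000/4000 has 6 bases of homology
  piece <- substr(base, 3995, 4000)
  ref <- c(chr1 = paste0(substr(base, 1, 2000), revcomp(piece),
                         substr(base, 2007, 5000)))
  h <- junction_homology(ref, "chr1", 2000, "+", "chr1", 4000, "+")
  expect_gte(h$homlen, 6)
})

test_that("annotate_homology centres the nominal position and sets CIPOS", {
  genome <- sim_genome(20000, seed = 76)
  events <- tibble::tibble(type = "DEL", chrom = "chr1", pos = 8000L,
                           size = 500L, hom_len = 4L)
  pl <- sim_plant_svs(genome, events, seed = 77)
  tr <- pl$truth
  call <- tibble::tibble(
    chrom_l = "chr1", start_l = tr$hom_lo, end_l = tr$hom_hi, dir_l = "+",
    chrom_h = "chr1", start_h = tr$pos_h - (tr$pos_l - tr$hom_lo),
    end_h = tr$pos_h + (tr$hom_hi - tr$pos_l), dir_h = "-",
    qual = 100, n_sr = 2L, n_as = 0L, untemplated = "")
  ann <- annotate_homology(call, pl$reference)
  expect_equal(ann$homlen, 4)
  expect_equal(ann$cipos_hi - ann$cipos_lo, 4)
  # nominal position is the floored centre of the homology interval
  expect_equal(ann$pos_l, tr$hom_lo + floor((tr$hom_hi - tr$hom_lo) / 2))
  expect_true(ann$pos_l >= tr$hom_lo && ann$pos_l <= tr$hom_hi)
  # inexact homology interval contains CIPOS
  expect_lte(ann$ihom_lo, ann$cipos_lo)
  expect_gte(ann$ihom_hi, ann$cipos_hi)
})

test_that("interval-only calls keep their evidence interval and no homology fields", {
  ref <- c(chr1 = strrep("ACGT", 2500))
  call <- tibble::tibble(
    chrom_l = "chr1", start_l = 900, end_l = 1100, dir_l = "+",
    chrom_h = "chr1", start_h = 2900, end_h = 3100, dir_h = "-",
    qual = 50, n_sr = 0L, n_as = 0L, untemplated = "")
  ann <- annotate_homology(call, ref)
  expect_true(is.na(ann$homlen))
  expect_equal(ann$pos_l, 1000)
  expect_equal(c(ann$cipos_lo, ann$cipos_hi), c(-100, 100))
})

test_that("confidence requires both assembly sides and the quality threshold", {
  calls <- tibble::tibble(qual = c(600, 600, 400, 700),
                          assembly_sides = c(2L, 1L, 2L, 0L))
  out <- classify_confidence(calls, qual_threshold = 500)
  expect_equal(out$confidence, c("HIGH", "LOW", "LOW", "LOW"))
})
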