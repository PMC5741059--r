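# Synthetic-data generator.

test_that("genome generation is deterministic and honours composition", {
  g1 <- sim_genome(2000, seed = 9)
  g2 <- sim_genome(2000, seed = 9)
  expect_identical(g1, g2)
  expect_false(identical(g1, sim_genome(2000, seed = 10)))
  at_only <- sim_genome(5000, gc = 0, seed = 1)
  expect_true(grepl("^[AT]+$", at_only[["chr1"]]))
  big <- sim_genome(100000, gc = 0.5, seed = 2)
  gc_frac <- mean(strsplit(big[["chr1"]], "")[[1]] %in% c("G", "C"))
  # within 3 sd of the binomial expectation
  expect_lt(abs(gc_frac - 0.5), 3 * sqrt(0.25 / 100000))
})

test_that("planted events change genome length exactly as specified", {
  genome <- sim_genome(30000, seed = 11)
  del <- sim_plant_svs(genome, tibble::tibble(
    type = "DEL", chrom = "chr1", pos = 10000L, size = 500L))
  expect_equal(nchar(del$mutated[["chr1"]]), 30000 - 500)
  dup <- sim_plant_svs(genome, tibble::tibble(
    type = "DUP", chrom = "chr1", pos = 10000L, size = 1000L))
  expect_equal(nchar(dup$mutated[["chr1"]]), 30000 + 1000)
  inv <- sim_plant_svs(genome, tibble::tibble(
    type = "INV", chrom = "chr1", pos = 10000L, size = 2000L))
  expect_equal(nchar(inv$mutated[["chr1"]]), 30000)
  ins <- sim_plant_svs(genome, tibble::tibble(
    type = "INS", chrom = "chr1", pos = 10000L, size = 0L, seq = "GATTACA"))
  expect_equal(nchar(ins$mutated[["chr1"]]), 30000 + 7)
  expect_error(sim_plant_svs(genome, tibble::tibble(
    type = c("DEL", "DEL"), chrom = "chr1", pos = c(10000L, 10200L),
    size = c(500L, 500L))), "overlap")
})

test_that("truth junctions carry the planted directions per event class", {
  genome <- sim_genome(c(30000, 20000), seed = 12)
  ev <- tibble::tibble(
    type = c("DEL", "DUP", "INV", "TRA"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(5000L, 12000L, 20000L, 10000L),
    size = c(500L, 1000L, 2000L, 0L),
    chrom2 = c(NA, NA, NA, NA), pos2 = c(NA, NA, NA, NA))
  # TRA needs its own pair of chromosomes
  genome3 <- sim_genome(c(30000, 10000, 10000), seed = 12)
  ev$chrom2[4] <- "chr3"; ev$pos2[4] <- 5000L
  pl <- sim_plant_svs(genome3, ev)
  tr <- pl$truth
  del <- tr[tr$type == "DEL", ]
  expect_equal(c(del$dir_l, del$dir_h), c("+", "-"))
  dup <- tr[tr$type == "DUP", ]
  expect_equal(c(dup$dir_l, dup$dir_h), c("-", "+"))
  inv <- tr[tr$type == "INV", ]
  expect_setequal(paste0(inv$dir_l, inv$dir_h), c("++", "--"))
  tra <- tr[tr$type == "TRA", ]
  expect_equal(nrow(tra), 2)     # reciprocal
  expect_setequal(tra$chrom_l, "chr2")
  expect_setequal(tra$chrom_h, "chr3")
})

test_that("error-free reads substring-match their source haplotype", {
  genome <- sim_genome(15000, seed = 13)
  aln <- sim_reads(list(genome), list(NULL), coverage = 3, error_rate = 0,
                   seed = 14)
  hap <- genome[["chr1"]]
  for (i in sample(nrow(aln), 25)) {
    r <- aln[i, ]
    fwd <- if (bitwAnd(r$flag, 16L) > 0) r$seq else r$seq
    expect_true(grepl(fwd, hap, fixed = TRUE))   # SEQ is reference-forward
  }
})

test_that("read count tracks coverage and output is byte-identical for a seed", {
  genome <- sim_genome(10000, seed = 15)
  aln <- sim_reads(list(genome), list(NULL), coverage = 10, seed = 16)
  expected_pairs <- 10 * 10000 / (2 * 100)
  expect_lte(abs(nrow(aln) / 2 - expected_pairs), 1)
  aln2 <- sim_reads(list(genome), list(NULL), coverage = 10, seed = 16)
  expect_identical(aln, aln2)
  expect_error(sim_reads(list(genome), list(NULL), coverage = 0, seed = 1),
               "coverage")
})

test_that("SAM output round-trips through samtools-compatible readers", {
  fx <- small_del_dataset(seed = 17, coverage = 6)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(fx$aln, fx$plant$reference, path)
  back <- read_alignments(path)
  expect_equal(nrow(back), nrow(fx$aln))
  m1 <- collect_metrics(fx$aln)
  m2 <- collect_metrics(path)
  expect_equal(m2$concordant_lo, m1$concordant_lo)
  expect_equal(m2$concordant_hi, m1$concordant_hi)
  expect_equal(m2$read_counts$total_reads, m1$read_counts$total_reads)
})

test_that("junction-crossing reads are soft-clipped at the junction", {
  fx <- small_del_dataset(seed = 18, coverage = 20, hom_len = 0L)
  del_pos <- fx$events$pos
  clipped <- fx$aln[grepl("S", fx$aln$cigar), ]
  expect_gt(nrow(clipped), 0)
  # right-clipped reads at the deletion end exactly at the junction
  cl <- breakendr:::cigar_clip(clipped$cigar)
  refw <- breakendr:::cigar_ref_width(clipped$cigar)
  ends <- clipped$pos + refw - 1
  right_at_del <- clipped[cl$trail > 0 & abs(ends - del_pos) <= 4, ]
  expect_gt(nrow(right_at_del), 0)
})
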