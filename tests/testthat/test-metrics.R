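# Library metrics collection.

# minimal alignment tibble builder: proper FR pairs with the given fragment
# sizes on a 100 kb chromosome
pair_aln <- function(frag_sizes, read_len = 100, chrom = "chr1") {
  n <- length(frag_sizes)
  start <- seq(1000, by = 5, length.out = n)
  r1 <- tibble::tibble(
    qname = sprintf("p%05d", seq_len(n)), flag = 99L, chrom = chrom,
    pos = start, mapq = 60L, cigar = paste0(read_len, "M"),
    mchrom = chrom, mpos = start + frag_sizes - read_len,
    seq = strrep("A", read_len), qual = strrep("I", read_len))
  r2 <- dplyr::mutate(r1, flag = 147L, pos = .data$mpos, mpos = start)
  dplyr::arrange(dplyr::bind_rows(r1, r2), pos)
}

test_that("a constant fragment-size library gives degenerate bounds and p_d 0", {
  aln <- pair_aln(rep(300, 100))
  m <- collect_metrics(aln)
  expect_equal(m$concordant_lo, 300)
  expect_equal(m$concordant_hi, 300)
  expect_equal(m$p_d, 0)
  expect_equal(m$read_counts$total_pairs, 100)
  expect_equal(m$read_counts$pairs_both_mapped, 100)
  expect_equal(sum(m$fragment_size_dist$prob), 1)
})

test_that("an empty input is an error", {
  expect_error(collect_metrics(pair_aln(300)[0, ]), "no reads")
})

test_that("concordance bounds match sort-based order statistics on simulated sizes", {
  set.seed(1234)
  sizes <- pmax(150, round(rnorm(10000, 300, 30)))
  m <- collect_metrics(pair_aln(sizes), concordance_percentile = 0.995)
  # oracle: sort and index the simulated sizes directly
  srt <- sort(sizes)
  n <- length(srt)
  expect_equal(m$concordant_lo, srt[ceiling(n * 0.0025)])
  expect_equal(m$concordant_hi, srt[ceiling(n * 0.9975)])
  # symmetric concordance invariant
  frac_out <- mean(sizes < m$concordant_lo | sizes > m$concordant_hi)
  expect_lte(frac_out, 1 - 0.995 + 2 / n)
  # p_d from median +/- 10 raw MADs
  med <- median(sizes); madr <- mad(sizes, constant = 1)
  expect_equal(m$p_d, mean(abs(sizes - med) > 10 * madr))
})

test_that("p_u is the one-end-anchored pair rate and unpaired metrics disable pair evidence", {
  aln <- pair_aln(rep(300, 50))
  # unmap one read of five pairs
  idx <- which(aln$qname %in% sprintf("p%05d", 1:5) & aln$flag == 147L)
  aln$flag[idx] <- 165L  # paired, unmapped, mate forward
  aln$cigar[idx] <- "*"
  m <- collect_metrics(aln)
  expect_equal(m$p_u, 5 / 50)
  expect_equal(m$read_counts$pairs_one_mapped, 5)
  # all pairs broken: pair-based evidence disabled with a warning
  aln2 <- pair_aln(rep(300, 10))
  aln2$flag[aln2$flag == 147L] <- 165L
  aln2$cigar[aln2$flag == 165L] <- "*"
  expect_warning(m2 <- collect_metrics(aln2), "disabled")
  expect_false(m2$pairs_available)
})

test_that("distribution tails floor at the pseudo-count for unseen lengths", {
  m <- collect_metrics(pair_aln(rep(300, 200)))
  tail_far <- breakendr:::tail_mass_two_sided(m$fragment_size_dist, 5000,
                                              m$n_fragments)
  expect_equal(tail_far, 1 / (2 * m$n_fragments))
})

test_that("classification is pure and matches the definitional cases", {
  m <- collect_metrics(pair_aln(rep(300, 100)))
  conc <- list(mapped = TRUE, same_chrom = TRUE, proper_orientation = TRUE,
               ifs = 300)
  rd <- list(mapped = TRUE, cigar = "100M", paired = TRUE)
  expect_length(classify_read(rd, conc, m), 0)
  rd_sc <- list(mapped = TRUE, cigar = "50M50S", paired = TRUE)
  expect_equal(classify_read(rd_sc, conc, m), "SOFT_CLIP")
  rd_oea <- list(mapped = TRUE, cigar = "100M", paired = TRUE)
  oea_mate <- list(mapped = FALSE)
  expect_equal(classify_read(rd_oea, oea_mate, m), "ONE_END_ANCHOR")
  both_un <- list(mapped = FALSE, cigar = "*", paired = TRUE)
  expect_length(classify_read(both_un, list(mapped = FALSE), m), 0)
  # discordant by size, by orientation, by chromosome
  expect_equal(classify_read(rd, list(mapped = TRUE, same_chrom = TRUE,
                                      proper_orientation = TRUE, ifs = 900),
                             m), "DISCORDANT_PAIR")
  expect_equal(classify_read(rd, list(mapped = TRUE, same_chrom = TRUE,
                                      proper_orientation = FALSE, ifs = 300),
                             m), "DISCORDANT_PAIR")
  expect_equal(classify_read(rd, list(mapped = TRUE, same_chrom = FALSE,
                                      proper_orientation = FALSE, ifs = Inf),
                             m), "DISCORDANT_PAIR")
  # purity: repeated calls agree
  for (i in 1:3) {
    expect_equal(classify_read(rd_sc, conc, m), "SOFT_CLIP")
  }
})
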