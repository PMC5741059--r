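# Probabilistic evidence scoring model.

fake_metrics <- function(sc_mass = NULL, frag = NULL, p_d = 0.01,
                         p_u = 0.02, del_mass = NULL) {
  structure(list(
    library_id = "test",
    softclip_len_dist = sc_mass,
    fragment_size_dist = frag,
    insertion_len_dist = del_mass,
    deletion_len_dist = del_mass,
    p_d = p_d, p_u = p_u,
    n_fragments = if (is.null(frag)) 0 else 1e6,
    n_softclips = if (is.null(sc_mass)) 0 else 1e6,
    n_insertions = 1e6, n_deletions = 1e6,
    pairs_available = !is.null(frag), mapq_cap = 60
  ), class = "sv_metrics")
}

point_mass <- function(value, at = value) tibble::tibble(value = at, prob = 1)

test_that("phred transform matches its definition and caps", {
  expect_equal(phred(1), 0)
  expect_equal(phred(0.1), 10)
  expect_equal(phred(0.001), 30)
  expect_equal(phred(0), 100)              # capped, not infinite
  expect_equal(phred(1e-30, q_max = 50), 50)
  expect_error(phred(-0.1), "probability")
  expect_error(phred(1.5), "probability")
  # inversion identity below the cap
  for (q in c(0, 3.2, 17.9, 55)) {
    expect_equal(phred(phred_inv(q)), q, tolerance = 1e-9)
  }
})

test_that("k-mer weight equals the printed joint-probability formula", {
  expect_equal(kmer_weight(10, 0), 0)       # mapq 0: argument of log is 1
  expect_equal(kmer_weight(c(2, 30, 40), 0), 0)
  expect_equal(kmer_weight(10, 10), -10 * log10(1 - 0.9 * 0.9),
               tolerance = 1e-6)            # ~7.21
  expect_equal(kmer_weight(c(20, 20), 30),
               -10 * log10(1 - 0.999 * 0.99^2), tolerance = 1e-6) # ~16.80
  # rolling whole-read version agrees with the direct evaluation
  bq <- c(30, 20, 25, 35, 15, 28)
  w <- kmer_weights_read(bq, 40, k = 3)
  direct <- vapply(1:4, function(i) kmer_weight(bq[i:(i + 2)], 40),
                   numeric(1))
  expect_equal(w, direct, tolerance = 1e-9)
})

test_that("split-read scoring combines mapping and clip-length terms", {
  m <- fake_metrics(sc_mass = point_mass(20))
  # any mapq of zero makes the evidence worthless
  expect_equal(score_split_read(20, 0, 60, m), 0)
  expect_equal(score_split_read(20, 60, 0, m), 0)
  # full clip-length mass: observing the clip is unsurprising
  expect_equal(score_split_read(20, 60, 60, m), 0, tolerance = 0.01)
  # certain mapping with mass 0.01 gives q = 20
  m2 <- fake_metrics(sc_mass = tibble::tibble(value = c(5, 20),
                                              prob = c(0.99, 0.01)))
  expect_equal(score_split_read(20, 1000, 1000, m2, q_max = 1000), 20,
               tolerance = 1e-6)
})

test_that("read-pair scoring uses p_d and the fragment-size tail", {
  frag <- tibble::tibble(value = c(300, 800), prob = c(0.999, 0.001))
  m <- fake_metrics(frag = frag, p_d = 0.05)
  expect_equal(score_read_pair(800, 0, 60, m), 0)
  # P_rp(ifs) = 1 at the median: q = 0 regardless of p_d
  expect_equal(score_read_pair(300, 1000, 1000, m, q_max = 1000), 0,
               tolerance = 1e-6)
  # certain mapping, p_d = 0.01, tail mass ~0: q = 20
  m2 <- fake_metrics(frag = point_mass(300), p_d = 0.01)
  q <- score_read_pair(1e9, 1000, 1000, m2, q_max = 1000)
  expect_equal(q, -10 * log10(0.01 + 0.99 * 5e-7), tolerance = 1e-3)
  expect_equal(round(q), 20)
  # DP without a fragment distribution is an error, OEA still scorable
  m3 <- fake_metrics(frag = NULL)
  expect_error(score_read_pair(500, 60, 60, m3), "fragment")
  expect_gt(score_read_pair(NA, 60, NULL, m3, kind = "ONE_END_ANCHOR"), 0)
})

test_that("indel scoring swaps in the operation-length distribution", {
  m <- fake_metrics(del_mass = point_mass(10))
  expect_equal(score_indel_read("D", 10, 60, m), 0, tolerance = 0.01)
  expect_equal(score_indel_read("D", 10, 0, m), 0)
  m2 <- fake_metrics(del_mass = tibble::tibble(value = c(1, 10),
                                               prob = c(0.999, 0.001)))
  expect_equal(score_indel_read("D", 10, 1000, m2, q_max = 1000), 30,
               tolerance = 1e-6)
})

test_that("assembly score is the maximum promoted constituent term", {
  m <- fake_metrics(sc_mass = tibble::tibble(value = c(5, 20),
                                             prob = c(0.99, 0.01)),
                    frag = point_mass(300), p_d = 0.01)
  cons <- tibble::tibble(
    kind = c("SOFT_CLIP", "DISCORDANT_PAIR", "ONE_END_ANCHOR"),
    mapq_a = c(40, 55, 30), l_sc = c(20, NA, NA), ifs = c(NA, 1e9, NA))
  q <- score_assembly(cons, realign_mapq = 60, m)
  # oracle: elementwise max over the promoted per-constituent scores, all
  # with mapq_a = max constituent mapq and mapq_b = realignment mapq
  mx <- max(cons$mapq_a)
  pm <- (1 - 10^(-mx / 10)) * (1 - 10^(-60 / 10))
  terms <- c(
    score_split_read(20, mx, 60, m),
    score_read_pair(1e9, mx, 60, m),
    phred(pm * m$p_u + (1 - pm))
  )
  expect_equal(q, max(terms), tolerance = 1e-9)
  # all constituents mapq 0
  cons0 <- dplyr::mutate(cons, mapq_a = 0)
  expect_equal(score_assembly(cons0, 60, m), 0)
  # single constituent equals its own promoted score
  expect_equal(score_assembly(cons[1, ], 60, m),
               score_split_read(20, 40, 60, m))
  expect_error(score_assembly(cons[0, ], 60, m), "empty")
})

test_that("scores are monotone in mapping quality and distribution mass", {
  m_hi <- fake_metrics(sc_mass = tibble::tibble(value = c(5, 20),
                                                prob = c(0.5, 0.5)))
  m_lo <- fake_metrics(sc_mass = tibble::tibble(value = c(5, 20),
                                                prob = c(0.99, 0.01)))
  qs <- vapply(c(0, 10, 20, 40, 60), function(mq) {
    score_split_read(20, mq, 60, m_lo)
  }, numeric(1))
  expect_true(all(diff(qs) >= 0))
  # more mass at the observed clip length means a lower score
  expect_lte(score_split_read(20, 60, 60, m_hi),
             score_split_read(20, 60, 60, m_lo))
  frag <- tibble::tibble(value = c(250, 300, 350), prob = c(.25, .5, .25))
  m <- fake_metrics(frag = frag, p_d = 0.001)
  q_tail <- score_read_pair(1000, 60, 60, m)
  q_mid <- score_read_pair(300, 60, 60, m)
  expect_lte(q_mid, q_tail)
})
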