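# Maximal-clique variant calling and greedy assignment.

bp_row <- function(s_l, e_l, s_h, e_h, dir_l = "+", dir_h = "-", w = 10,
                   id = NULL) {
  tibble::tibble(chrom_l = "chr1", s_l = s_l, e_l = e_l, dir_l = dir_l,
                 chrom_h = "chr1", s_h = s_h, e_h = e_h, dir_h = dir_h,
                 w = w, read_id = id %||% paste0("e", s_l, "_", s_h),
                 untemplated = "", origin = "SR")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single and identical evidence form the expected cliques", {
  cl1 <- enumerate_maximal_cliques(bp_row(10, 20, 110, 120, w = 7))
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$weight, 7)
  two <- dplyr::bind_rows(bp_row(10, 20, 110, 120, w = 7, id = "a"),
                          bp_row(10, 20, 110, 120, w = 5, id = "b"))
  cl2 <- enumerate_maximal_cliques(two)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$weight, 12)
  expect_length(cl2$members[[1]], 2)
})

test_that("the clique interval is the intersection of member rectangles", {
  two <- dplyr::bind_rows(bp_row(10, 30, 100, 130, id = "a"),
                          bp_row(20, 40, 120, 150, id = "b"))
  cl <- enumerate_maximal_cliques(two)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start_l, cl$end_l), c(20, 30))
  expect_equal(c(cl$start_h, cl$end_h), c(120, 130))
})

test_that("random rectangle instances match exhaustive subset enumeration", {
  set.seed(60)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    s_l <- sample(1:30, n, replace = TRUE); e_l <- s_l + sample(0:15, n, TRUE)
    s_h <- sample(1:30, n, replace = TRUE); e_h <- s_h + sample(0:15, n, TRUE)
    got <- breakendr:::rectangle_cliques(s_l, e_l, s_h, e_h)
    want <- brute_force_rect_cliques(s_l, e_l, s_h, e_h)
    norm <- function(x) sort(vapply(x, paste, character(1), collapse = ","))
    expect_equal(norm(got), norm(want),
                 info = sprintf("instance %d", rep))
  }
})

test_that("directional subsets never mix", {
  ev <- dplyr::bind_rows(
    bp_row(10, 20, 110, 120, "+", "-", id = "a"),
    bp_row(10, 20, 110, 120, "+", "+", id = "b"),
    bp_row(10, 20, 110, 120, "-", "-", id = "c"))
  cl <- enumerate_maximal_cliques(ev)
  expect_equal(nrow(cl), 3)
  expect_equal(anyDuplicated(paste(cl$dir_l, cl$dir_h)), 0)
})

test_that("greedy assignment gives each evidence to its best clique and conserves weight", {
  # e_mid overlaps both a heavy and a light clique
  ev <- dplyr::bind_rows(
    bp_row(10, 20, 100, 110, w = 60, id = "heavy1"),
    bp_row(12, 22, 102, 112, w = 40, id = "heavy2"),
    bp_row(18, 40, 108, 140, w = 10, id = "mid"),
    bp_row(35, 45, 135, 145, w = 20, id = "light"))
  cl <- enumerate_maximal_cliques(ev)
  calls <- greedy_assign(cl, ev)
  expect_equal(sum(calls$qual), sum(ev$w))       # conservation
  # each evidence appears exactly once across calls
  members <- unlist(calls$members)
  expect_equal(anyDuplicated(members), 0)
  expect_setequal(members, seq_len(nrow(ev)))
  # the shared item went to the provisionally heavier clique
  heavy_call <- calls[which.max(calls$qual), ]
  expect_true(3 %in% heavy_call$members[[1]])
  expect_equal(heavy_call$qual, 110)
})

test_that("ties in greedy assignment resolve to the genomically first variant", {
  ev <- dplyr::bind_rows(
    bp_row(10, 20, 100, 110, w = 50, id = "a"),
    bp_row(30, 40, 130, 140, w = 50, id = "b"),
    bp_row(15, 35, 105, 135, w = 5, id = "shared"))
  cl <- enumerate_maximal_cliques(ev)
  calls <- greedy_assign(cl, ev)
  shared_call <- calls[vapply(calls$members, function(m) 3 %in% m,
                              logical(1)), ]
  expect_equal(shared_call$start_l, 15)  # the first clique in genome order
})

test_that("variants keeping no evidence are dropped", {
  ev <- dplyr::bind_rows(
    bp_row(10, 30, 100, 130, w = 100, id = "a"),
    bp_row(20, 40, 110, 140, w = 90, id = "b"))
  cl <- enumerate_maximal_cliques(ev)
  calls <- greedy_assign(cl, ev)
  # both items land in the overlap clique; flank-only cliques vanish
  expect_true(all(vapply(calls$members, length, integer(1)) > 0))
  expect_equal(sum(calls$qual), 190)
})
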