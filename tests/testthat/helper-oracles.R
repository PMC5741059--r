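suppressMessages(library(dplyr))

# Independent oracles used across the suite. These deliberately use naive
# algorithms (exhaustive enumeration, quadratic DP) so they stay independent
# of the implementation paths they check.

# all maximal cliques of a rectangle set by exhaustive subset enumeration
brute_force_rect_cliques <- function(s_l, e_l, s_h, e_h) {
  n <- length(s_l)
  overlap <- function(i, j) {
    max(s_l[i], s_l[j]) <= min(e_l[i], e_l[j]) &&
      max(s_h[i], s_h[j]) <= min(e_h[i], e_h[j])
  }
  adj <- outer(seq_len(n), seq_len(n), Vectorize(overlap))
  is_clique <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    all(adj[idx, idx])
  }
  cliques <- list()
  for (m in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0 || !is_clique(idx)) next
    # maximal: no vertex outside idx connected to all of idx
    ext <- setdiff(seq_len(n), idx)
    if (length(ext) == 0 ||
        !any(vapply(ext, function(v) all(adj[v, idx]), logical(1)))) {
      cliques[[length(cliques) + 1]] <- idx
    }
  }
  unique(cliques)
}

# exhaustive enumeration of every path in a positional graph (node tibble +
# edge list); returns the maximum total path weight
brute_force_max_path <- function(nodes, edges) {
  n <- nrow(nodes)
  succ <- vector("list", n)
  if (nrow(edges) > 0) {
    sp <- split(edges$to_idx, edges$from_idx)
    succ[as.integer(names(sp))] <- sp
  }
  best <- -Inf
  walk <- function(i, w) {
    w <- w + nodes$weight[i]
    best <<- max(best, w)
    for (s in succ[[i]]) walk(s, w)
  }
  for (i in seq_len(n)) walk(i, 0)
  best
}

# quadratic affine-gap local alignment DP in plain R (score only)
r_dp_local_score <- function(q, r, match = 1, mismatch = -4,
                             gap_open = -6, gap_extend = -1) {
  qn <- strsplit(q, "")[[1]]; rn <- strsplit(r, "")[[1]]
  n <- length(qn); m <- length(rn)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  go <- abs(gap_open); ge <- abs(gap_extend)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      s <- if (qn[i - 1] == rn[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# direct character-level homology scan at a deletion junction (independent of
# junction_homology): bases following pos_l on the reference equal bases
# following the junction partner
scan_del_homology <- function(ref, pos_l, pos_h) {
  right <- 0
  while (substr(ref, pos_l + right + 1, pos_l + right + 1) ==
         substr(ref, pos_h + right, pos_h + right) &&
         substr(ref, pos_l + right + 1, pos_l + right + 1) != "") {
    right <- right + 1
  }
  left <- 0
  while (substr(ref, pos_l - left, pos_l - left) ==
         substr(ref, pos_h - left - 1, pos_h - left - 1) &&
         substr(ref, pos_l - left, pos_l - left) != "") {
    left <- left + 1
  }
  list(left = left, right = right, homlen = left + right)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a tiny deletion dataset reused by several files
small_del_dataset <- function(seed = 3, genome_len = 20000, coverage = 30,
                              hom_len = 4L) {
  genome <- sim_genome(genome_len, seed = seed)
  events <- tibble::tibble(type = "DEL", chrom = "chr1",
                           pos = as.integer(genome_len * 0.4),
                           size = 500L, hom_len = hom_len)
  pl <- sim_plant_svs(genome, events, seed = seed + 1)
  aln <- sim_reads(list(pl$reference, pl$mutated), list(NULL, pl$segments),
                   coverage = coverage, seed = seed + 2)
  list(plant = pl, aln = aln, events = events)
}
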