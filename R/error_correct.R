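# Assembly graph error correction: bubble popping and leaf collapse.
#
# A path A is collapsed into an alternate path B when
#   * total weight of A < total weight of B,
#   * the spelled bases of A and B differ in fewer than `max_base_diff`
#     positions (Hamming; bubble paths are equal length by construction,
#     leaves are compared over the overlap), and
#   * A and B are simple bubbles (same start and end node, equal length) or A
#     is a terminal leaf sharing its start (or end) node with B,
# and only for paths shorter than `max_path_len` nodes (default twice the
# read length). Collapsing transfers A's support (and hence weight) onto the
# corresponding nodes of B; total graph weight is conserved.

# Walk a branchless run starting from `start_idx` (which must be a successor /
# predecessor of a fork); returns interior node indices and how it ended.
walk_branchless <- function(start_idx, nxt_edges, indeg, outdeg, max_len,
                            forward = TRUE) {
  path <- integer(0)
  cur <- start_idx
  repeat {
    din <- if (forward) indeg[cur] else outdeg[cur]
    if (length(path) > 0 && din >= 2) {
      return(list(interior = path, end = "join", join = cur))
    }
    path <- c(path, cur)
    if (length(path) > max_len) return(list(interior = path, end = "long"))
    dout <- if (forward) outdeg[cur] else indeg[cur]
    if (dout == 0) return(list(interior = path, end = "leaf"))
    if (dout >= 2) return(list(interior = path, end = "fork"))
    cur <- nxt_edges[[cur]]
  }
}

# spelled "difference bases" of a path: last base of each node when aligned at
# the start, first base when aligned at the end
path_diff_bases <- function(nodes, idx, k, from_start = TRUE) {
  if (from_start) nodes$code[idx] %% 4
  else nodes$code[idx] %/% (4^(k - 1))
}

#' Error-correct a positional de Bruijn graph
#'
#' Collapses simple bubbles and terminal leaves into heavier alternate paths
#' (see file header for the criteria). Performed iteratively until no further
#' collapse applies.
#'
#' @param g An `sv_graph`.
#' @param max_base_diff Paths are merged only when they differ in fewer than
#'   this many bases (default 2, i.e. at most one base).
#' @param max_path_len Maximum path length (in nodes) eligible for
#'   correction; default twice `read_len`.
#' @param read_len Library read length used for the default `max_path_len`.
#' @param max_iter Safety bound on collapse iterations.
#' @return The corrected graph.
#' @export
pg_error_correct <- function(g, max_base_diff = 2, max_path_len = NULL,
                             read_len = 100, max_iter = 100L) {
  if (is.null(max_path_len)) max_path_len <- 2L * read_len
  for (iter in seq_len(max_iter)) {
    ms <- find_collapses(g, max_base_diff, max_path_len)
    if (length(ms) == 0) break
    # batch is node-disjoint, so all remaps apply as one mapping
    m <- list(from = bind_rows(lapply(ms, `[[`, "from")),
              to = bind_rows(lapply(ms, `[[`, "to")))
    g <- apply_collapse(g, m)
  }
  g
}

# Locate a batch of node-disjoint (A -> B) collapses in one graph traversal;
# returns an empty list when the graph is clean. The search is deterministic:
# forks are visited in (position, k-mer) order, and a node takes part in at
# most one collapse per batch (as source or as target of a source).
find_collapses <- function(g, max_base_diff, max_path_len) {
  nodes <- pg_nodes(g)
  if (nrow(nodes) < 2) return(list())
  k <- g$k
  ed <- pg_edges(nodes, k)
  n <- nrow(nodes)
  indeg <- tabulate(ed$to_idx, n)
  outdeg <- tabulate(ed$from_idx, n)
  succ <- vector("list", n); pred <- vector("list", n)
  if (nrow(ed) > 0) {
    sp <- split(ed$to_idx, ed$from_idx)
    succ[as.integer(names(sp))] <- sp
    sp <- split(ed$from_idx, ed$to_idx)
    pred[as.integer(names(sp))] <- sp
  }
  # single-successor lookup for branchless walking
  nxt_f <- lapply(succ, function(s) if (length(s) == 1) s else NA_integer_)
  nxt_b <- lapply(pred, function(s) if (length(s) == 1) s else NA_integer_)

  found <- list()
  busy <- logical(nrow(nodes))   # nodes already in a collapse this batch

  try_side <- function(forward) {
    deg <- if (forward) outdeg else indeg
    forks <- which(deg >= 2)
    if (length(forks) == 0) return(invisible())
    forks <- forks[order(nodes$pos[forks], nodes$code[forks])]
    for (u in forks) {
      branches <- sort(if (forward) succ[[u]] else pred[[u]])
      paths <- lapply(branches, function(b) {
        walk_branchless(b, if (forward) nxt_f else nxt_b, indeg, outdeg,
                        max_path_len, forward)
      })
      lens <- vapply(paths, function(p) length(p$interior), integer(1))
      wts <- vapply(paths, function(p) sum(nodes$weight[p$interior]), numeric(1))
      ends <- vapply(paths, function(p) p$end, character(1))
      joins <- vapply(paths, function(p) {
        if (p$end == "join") p$join else NA_integer_
      }, integer(1))
      np <- length(paths)
      for (i in seq_len(np)) {
        if (ends[i] == "long") next
        for (j in seq_len(np)) {
          if (i == j || ends[j] == "long") next
          # candidate: collapse A = paths[[i]] into B = paths[[j]]
          a <- paths[[i]]; b <- paths[[j]]
          is_bubble <- a$end == "join" && b$end == "join" &&
            joins[i] == joins[j] && lens[i] == lens[j]
          is_leaf <- a$end == "leaf" && lens[j] >= lens[i]
          if (!is_bubble && !is_leaf) next
          # A must be fully branchless so no external path runs through it
          first_deg <- if (forward) indeg[a$interior[1]] else outdeg[a$interior[1]]
          if (first_deg != 1) next
          ov <- lens[i]
          bi_full <- b$interior[seq_len(ov)]
          if (any(busy[a$interior]) || any(busy[bi_full])) next
          wa <- wts[i]
          wb <- sum(nodes$weight[bi_full])
          if (!(wa < wb)) next
          da <- path_diff_bases(nodes, a$interior, k, from_start = forward)
          db <- path_diff_bases(nodes, bi_full, k, from_start = forward)
          if (sum(da != db) >= max_base_diff) next
          # positions agree pairwise by construction: both branches advance
          # one base per step from u
          ai <- a$interior; bi <- bi_full
          if (!forward) { ai <- rev(ai); bi <- rev(bi) }
          busy[c(a$interior, bi_full)] <<- TRUE
          found[[length(found) + 1]] <<- list(
            from = nodes[ai, c("pos", "code")],
            to = nodes[bi, c("pos", "code")]
          )
          break  # this branch is consumed; move to the next fork
        }
      }
    }
    invisible()
  }
  try_side(forward = TRUE)
  try_side(forward = FALSE)
  found
}

# Remap the support and transition rows of the collapsed nodes onto the
# target path. Weight rows are retained (only the k-mer changes), so total
# graph weight is conserved.
apply_collapse <- function(g, m) {
  from <- tibble(pos = m$from$pos, code = m$from$code)
  hit <- vctrs::vec_match(g$support[, c("pos", "code")], from)
  sel <- !is.na(hit)
  g$support$code[sel] <- m$to$code[hit[sel]]
  if (nrow(g$trans) > 0) {
    ha <- vctrs::vec_match(
      tibble(pos = g$trans$pos, code = g$trans$from), from)
    sa <- !is.na(ha)
    g$trans$from[sa] <- m$to$code[ha[sa]]
    hb <- vctrs::vec_match(
      tibble(pos = g$trans$pos + 1, code = g$trans$to), from)
    sb <- !is.na(hb)
    g$trans$to[sb] <- m$to$code[hb[sb]]
    g$trans <- distinct(g$trans)
  }
  g
}
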