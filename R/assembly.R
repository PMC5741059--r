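# Break-end contig assembly.
#
# A break-end contig is a maximal-weight path of adjacent unanchored nodes,
# optionally flanked by anchored nodes. Anchored-flanked paths are called
# before unflanked paths; after each call all reads supporting any unanchored
# k-mer of the contig are removed from the graph, so each read contributes to
# a single assembly only; calling iterates until no unanchored k-mers remain.
#
# K-mer chaining truncation is applied during path calling: an edge may only
# be traversed when some supporting read contains that k-mer transition at
# that placement. This prevents looping misassembly through repeated k-mers
# (a self-intersecting read otherwise loops for as long as its placement
# window allows) and is a no-op for correctly assembled contigs, whose every
# transition is witnessed by a constituent read.

# Maximal-weight path DP over a DAG of positional nodes.
# nodes: tibble(pos, code, weight); edges: tibble(from_idx, to_idx);
# can_start: logical, nodes allowed to begin a path; flank_start: logical,
# nodes that begin an anchored-flanked path. Returns list(idx, weight,
# flanked) or NULL. Deterministic: ties resolved toward the smaller
# (position, k-mer code).
max_weight_path <- function(nodes, edges, flank_start = NULL) {
  n <- nrow(nodes)
  if (n == 0) return(NULL)
  if (is.null(flank_start)) flank_start <- rep(FALSE, n)
  # nodes must arrive topologically ordered (position, then code); reorder
  # defensively, mapping edges along
  ord <- order(nodes$pos, nodes$code)
  if (is.unsorted(ord)) {
    rank <- integer(n); rank[ord] <- seq_len(n)
    nodes <- nodes[ord, ]
    edges <- tibble(from_idx = rank[edges$from_idx],
                    to_idx = rank[edges$to_idx])
    flank_start <- flank_start[ord]
    inv <- ord
  } else {
    inv <- seq_len(n)
  }
  if (nrow(edges) > 0) {
    eo <- order(edges$to_idx, nodes$code[edges$from_idx])
    edges <- edges[eo, ]
  }
  dp <- max_path_dp_cpp(nodes$weight, edges$from_idx, edges$to_idx,
                        flank_start)
  best <- dp$best; bp <- dp$bp; best_f <- dp$best_f; bp_f <- dp$bp_f
  pick_end <- function(score) {
    cand <- which(is.finite(score) & score == max(score[is.finite(score)]))
    cand[order(nodes$pos[cand], nodes$code[cand])][1]
  }
  flanked <- any(is.finite(best_f))
  if (flanked) {
    e <- pick_end(best_f); wgt <- best_f[e]; ptr <- bp_f
  } else {
    e <- pick_end(best); wgt <- best[e]; ptr <- bp
  }
  path <- e
  if (flanked) {
    while (bp_f[path[1]] != 0) path <- c(bp_f[path[1]], path)
  } else {
    while (bp[path[1]] != 0) path <- c(bp[path[1]], path)
  }
  list(idx = inv[path], weight = wgt, flanked = flanked)
}

# spell the base sequence of a path of k-mer codes
spell_path <- function(codes, k) {
  if (length(codes) == 0) return("")
  paste0(kmer_string(codes[1], k),
         paste(kmer_last_base(codes[-1]), collapse = ""))
}

#' Call break-end contigs from a positional de Bruijn graph
#'
#' Iteratively calls the maximal-weight unanchored path (anchored-flanked
#' paths first), extends it into flanking anchored nodes until the anchored
#' length exceeds both the read length and the unanchored path length,
#' removes all reads supporting any unanchored k-mer of the path, and repeats
#' until no unanchored k-mers remain. Contigs with fewer than `min_support`
#' reads, unflanked contigs spelling fewer than `read_len` bases, and contigs
#' spelling more than `max_contig_len` bases are filtered (their reads are
#' still consumed).
#'
#' @param g An `sv_graph` (error-corrected).
#' @param min_support Minimum supporting reads per contig (default 3).
#' @param read_len Library read length (bp).
#' @param max_contig_len Maximum spelled contig length; default
#'   `2 * (concordant_hi + read_len)` when `concordant_hi` is given, else
#'   unlimited.
#' @param concordant_hi Upper concordant fragment-size bound used for the
#'   default `max_contig_len`.
#' @param truncate Apply k-mer chaining truncation (default TRUE).
#' @return Tibble of contigs: `start_pos`, `n_nodes`, `anchor_nodes`, `seq`,
#'   `anchored_seq`, `unanchored_seq`, `total_weight`, `n_support` and a
#'   `support` list column of read ids. Positions are graph coordinates.
#' @export
pg_call_contigs <- function(g, min_support = 3, read_len = 100,
                            max_contig_len = NULL, concordant_hi = NULL,
                            truncate = TRUE) {
  if (is.null(max_contig_len)) {
    max_contig_len <- if (!is.null(concordant_hi))
      2 * (concordant_hi + read_len) else Inf
  }
  out <- list()
  repeat {
    nodes <- pg_nodes(g)
    un <- which(!nodes$anchored)
    if (length(un) == 0) break
    edges <- if (truncate) pg_supported_edges(g, nodes) else pg_edges(nodes, g$k)
    # DP over the unanchored subgraph
    sub_map <- integer(nrow(nodes)); sub_map[un] <- seq_along(un)
    sub_edges <- edges %>%
      filter(.data$from_idx %in% un, .data$to_idx %in% un) %>%
      mutate(from_idx = sub_map[.data$from_idx], to_idx = sub_map[.data$to_idx])
    anch_pred <- edges %>%
      filter(nodes$anchored[.data$from_idx], .data$to_idx %in% un)
    flank_start <- rep(FALSE, length(un))
    flank_start[sub_map[unique(anch_pred$to_idx)]] <- TRUE
    mp <- max_weight_path(nodes[un, c("pos", "code", "weight")],
                          sub_edges, flank_start)
    if (is.null(mp)) break
    upath <- un[mp$idx]
    # anchored extension from the path start
    apath <- integer(0)
    if (mp$flanked) {
      target <- max(read_len, length(upath))
      cur <- upath[1]
      pred_tab <- edges %>% filter(nodes$anchored[.data$from_idx])
      while (length(apath) <= target) {
        ps <- pred_tab$from_idx[pred_tab$to_idx == cur]
        if (length(ps) == 0) break
        ps <- ps[order(-nodes$weight[ps], nodes$code[ps])]
        apath <- c(ps[1], apath)
        cur <- ps[1]
        if (length(apath) > target) break
      }
    }
    path_idx <- c(apath, upath)
    codes <- nodes$code[path_idx]
    anchor_n <- length(apath)
    # supporting reads of the unanchored k-mers
    on_path <- vctrs::vec_in(g$support[, c("pos", "code")],
                             nodes[upath, c("pos", "code")])
    sup <- unique(g$support$read_id[on_path])
    g <- pg_remove_reads(g, sup)
    seq <- spell_path(codes, g$k)
    slen <- nchar(seq)
    flanked <- anchor_n > 0
    keep <- length(sup) >= min_support &&
      (flanked || slen >= read_len) &&
      slen <= max_contig_len
    if (keep) {
      out[[length(out) + 1]] <- tibble(
        start_pos = nodes$pos[path_idx[1]],
        n_nodes = length(path_idx),
        anchor_nodes = anchor_n,
        seq = seq,
        anchored_seq = if (flanked) substr(seq, 1, anchor_n + g$k - 1) else "",
        unanchored_seq = substr(seq, anchor_n + g$k, slen),
        total_weight = sum(nodes$weight[path_idx]),
        n_support = length(sup),
        support = list(sup)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(start_pos = numeric(0), n_nodes = integer(0),
                  anchor_nodes = integer(0), seq = character(0),
                  anchored_seq = character(0), unanchored_seq = character(0),
                  total_weight = numeric(0), n_support = integer(0),
                  support = list()))
  }
  bind_rows(out)
}

#' Truncate a called contig path by k-mer chaining of its supporting reads
#'
#' Recomputes the maximal-weight path over the subgraph induced by the path's
#' supporting reads, traversing only k-mer transitions witnessed by some
#' constituent read at that placement (anchored-flanked paths preferred, ties
#' toward the truncation start). A path every transition of which is
#' read-supported is returned unchanged.
#'
#' @param path Tibble with columns `pos`, `code` describing the called path.
#' @param g The `sv_graph` the path was called from.
#' @return Tibble (`pos`, `code`, `weight`, `anchored`) of the truncated path.
#' @export
truncate_contig <- function(path, g) {
  on_path <- vctrs::vec_in(g$support[, c("pos", "code")],
                           path[, c("pos", "code")])
  sup <- unique(g$support$read_id[on_path])
  sub <- g
  sub$support <- g$support[g$support$read_id %in% sup, ]
  nodes <- pg_nodes(sub)
  edges <- pg_supported_edges(sub, nodes)
  un <- which(!nodes$anchored)
  sub_map <- integer(nrow(nodes)); sub_map[un] <- seq_along(un)
  sub_edges <- edges %>%
    filter(.data$from_idx %in% un, .data$to_idx %in% un) %>%
    mutate(from_idx = sub_map[.data$from_idx], to_idx = sub_map[.data$to_idx])
  anch_pred <- edges %>%
    filter(nodes$anchored[.data$from_idx], .data$to_idx %in% un)
  flank_start <- rep(FALSE, length(un))
  flank_start[sub_map[unique(anch_pred$to_idx)]] <- TRUE
  mp <- max_weight_path(nodes[un, c("pos", "code", "weight")],
                        sub_edges, flank_start)
  if (is.null(mp)) return(nodes[0, c("pos", "code", "weight", "anchored")])
  nodes[un[mp$idx], c("pos", "code", "weight", "anchored")]
}

# ---- graph-read placement and cluster/streaming assembly --------------------

# Build an sv_graph from a tibble of graph-read specs (read_id, seq, baseq
# list-column, mapq, start_lo, start_hi, anch_lo, anch_hi). Rows are
# generated per read and bound once.
build_graph <- function(greads, k) {
  g <- pg_new(k)
  sup <- list(); tra <- list()
  for (i in seq_len(nrow(greads))) {
    r <- greads[i, ]
    if (nchar(r$seq) < k) next
    ab <- if (!is.na(r$anch_lo)) r$anch_lo:r$anch_hi else NULL
    rows <- gread_rows(k, r$seq, r$baseq[[1]], r$mapq, r$read_id,
                       starts = r$start_lo:r$start_hi, anchored_bases = ab)
    if (is.null(rows)) next
    sup[[length(sup) + 1]] <- rows$support
    if (!is.null(rows$trans)) tra[[length(tra) + 1]] <- rows$trans
  }
  if (length(sup) > 0) g$support <- bind_rows(g$support, bind_rows(sup))
  if (length(tra) > 0) g$trans <- bind_rows(g$trans, bind_rows(tra))
  g
}

assemble_cluster <- function(greads, k, min_support, read_len,
                             max_contig_len, concordant_hi,
                             error_correct = TRUE) {
  g <- build_graph(greads, k)
  if (error_correct) g <- pg_error_correct(g, read_len = read_len)
  pg_call_contigs(g, min_support = min_support, read_len = read_len,
                  max_contig_len = max_contig_len,
                  concordant_hi = concordant_hi)
}

#' Assemble break-end contigs from a coordinate-ordered stream of placed reads
#'
#' Single streaming pass: reads are accumulated into an active subgraph while
#' their node-position spans can still share or abut a node of the subgraph
#' (tracked as a frontier on the maximum span end); once the next read starts
#' beyond the frontier, no later read can alter any maximal path of the
#' active subgraph, which is therefore error-corrected and assembled, its
#' contigs emitted, and the frontier reset. Output is identical to building
#' one whole graph and assembling it in memory (`streaming = FALSE`).
#'
#' @param greads Tibble of graph-read placements with columns `read_id`,
#'   `seq`, `baseq` (list), `mapq`, `start_lo`, `start_hi`, `anch_lo`,
#'   `anch_hi`, ordered by `start_lo`.
#' @param k K-mer size.
#' @param min_support,read_len,max_contig_len,concordant_hi See
#'   [pg_call_contigs()].
#' @param streaming Use the windowed streaming pass (default) or one whole
#'   in-memory graph.
#' @param error_correct Apply [pg_error_correct()] before calling.
#' @return Contig tibble as [pg_call_contigs()], ordered by `start_pos`.
#' @export
assemble_streaming <- function(greads, k = 25, min_support = 3,
                               read_len = 100, max_contig_len = NULL,
                               concordant_hi = NULL, streaming = TRUE,
                               error_correct = TRUE) {
  if (nrow(greads) == 0) {
    return(assemble_cluster(greads, k, min_support, read_len,
                            max_contig_len, concordant_hi, error_correct))
  }
  if (is.unsorted(greads$start_lo)) {
    bad <- which(diff(greads$start_lo) < 0)[1] + 1
    abort(sprintf("evidence stream out of order at record %d (read %s)",
                  bad, greads$read_id[bad]))
  }
  if (!streaming) {
    res <- assemble_cluster(greads, k, min_support, read_len,
                            max_contig_len, concordant_hi, error_correct)
    return(res %>% arrange(.data$start_pos, .data$seq))
  }
  span_end <- greads$start_hi + nchar(greads$seq) - 1
  # frontier: a new cluster begins when a read starts more than one position
  # past every node span seen so far (nodes interact only at distance <= 1)
  frontier <- cummax(span_end)
  new_cluster <- c(TRUE, greads$start_lo[-1] > frontier[-nrow(greads)] + 1)
  cluster <- cumsum(new_cluster)
  res <- lapply(split(greads, cluster), function(gr) {
    assemble_cluster(gr, k, min_support, read_len, max_contig_len,
                     concordant_hi, error_correct)
  })
  bind_rows(res) %>% arrange(.data$start_pos, .data$seq)
}
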