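# Positional de Bruijn graph.
#
# Nodes are (k-mer, expected genomic position) pairs. Two nodes x, y are
# connected iff p_y = p_x + 1 and the last k-1 bases of x equal the first k-1
# bases of y, so every edge advances the position by exactly one base and the
# graph is acyclic.
#
# The graph is held as a long support table with one row per
# (position, k-mer, supporting read) contribution; node weight, the anchored
# flag and the support set are aggregates of this table. Read-supported k-mer
# transitions are recorded alongside for k-mer chaining truncation.

#' Create an empty positional de Bruijn graph
#'
#' @param k K-mer size (4--26; default 25).
#' @param direction `"forward"` (break after the anchor) or `"backward"`.
#' @return An `sv_graph` object.
#' @export
pg_new <- function(k = 25, direction = c("forward", "backward")) {
  if (k < 4 || k > 26) abort("k must be between 4 and 26")
  structure(
    list(
      k = k,
      direction = match.arg(direction),
      support = tibble(pos = numeric(0), code = numeric(0),
                       anchored = logical(0), read_id = character(0),
                       w = numeric(0)),
      trans = tibble(pos = numeric(0), from = numeric(0), to = numeric(0))
    ),
    class = "sv_graph"
  )
}

#' @export
print.sv_graph <- function(x, ...) {
  nd <- pg_nodes(x)
  cat("<positional de Bruijn graph>\n")
  cat("  k:", x$k, " direction:", x$direction, "\n")
  cat("  nodes:", nrow(nd), " reads:", dplyr::n_distinct(x$support$read_id), "\n")
  invisible(x)
}

#' Test whether two positional k-mer nodes are connected
#'
#' True iff the positions are adjacent (`pos_y == pos_x + 1`) and the last
#' k-1 bases of `kmer_x` equal the first k-1 bases of `kmer_y`.
#'
#' @param kmer_x,kmer_y K-mer strings of equal length.
#' @param pos_x,pos_y Expected genomic start positions.
#' @return Logical.
#' @examples
#' edge_exists("ACGT", 5, "CGTA", 6) # TRUE
#' @export
edge_exists <- function(kmer_x, pos_x, kmer_y, pos_y) {
  if (nchar(kmer_x) != nchar(kmer_y)) abort("k-mers must have equal length")
  k <- nchar(kmer_x)
  pos_y == pos_x + 1 &&
    substr(kmer_x, 2, k) == substr(kmer_y, 1, k - 1)
}

#' Add a read to a positional de Bruijn graph
#'
#' The read's k-mers are added at every candidate start position in
#' `starts` (a soft-clipped read has a single start, the position it would
#' start at were it fully mapped; a discordant-pair or one-end-anchor read has
#' one start per concordant placement of the fragment). K-mer `i` of a read
#' placed at start `s` lands at position `s + i - 1` with weight
#' [kmer_weight()] rounded to the nearest integer, and is flagged anchored iff
#' all of its bases are reference-aligned in this read (`anchored_bases`).
#' K-mers containing ambiguous bases are skipped.
#'
#' @param g An `sv_graph`.
#' @param seq Read bases (reference-forward orientation for the placement).
#' @param baseq Integer base qualities (recycled if length 1).
#' @param mapq Mapping quality used for the k-mer weights.
#' @param read_id Read identifier recorded in the support set.
#' @param starts Integer vector of candidate start positions.
#' @param anchored_bases Integer vector of 1-based read positions that are
#'   aligned to the reference, or `NULL` if none (multi-placement reads).
#' @return The updated graph.
#' @export
pg_add_read <- function(g, seq, baseq, mapq, read_id, starts,
                        anchored_bases = NULL) {
  rows <- gread_rows(g$k, seq, baseq, mapq, read_id, starts, anchored_bases)
  if (is.null(rows)) return(g)
  g$support <- dplyr::bind_rows(g$support, rows$support)
  g$trans <- dplyr::bind_rows(g$trans, rows$trans)
  g
}

# support/transition rows of one read placement (shared by pg_add_read and
# the batch graph builder)
gread_rows <- function(k, seq, baseq, mapq, read_id, starts,
                       anchored_bases = NULL) {
  n <- nchar(seq)
  if (n < k) {
    warn(sprintf("read %s shorter than k = %d; skipped", read_id, k))
    return(NULL)
  }
  codes <- kmer_codes(seq, k)
  if (length(baseq) == 1) baseq <- rep(baseq, n)
  w <- round(kmer_weights_read(baseq, mapq, k))
  idx <- which(!is.na(codes))
  if (length(idx) == 0) return(NULL)
  anch <- rep(FALSE, length(codes))
  if (!is.null(anchored_bases) && length(anchored_bases) > 0 &&
      length(starts) == 1) {
    ab <- range(anchored_bases)
    anch <- seq_along(codes) >= ab[1] & (seq_along(codes) + k - 1) <= ab[2]
  }
  ns <- length(starts)
  support <- tibble(
    pos = rep(starts, each = length(idx)) + rep(idx - 1, ns),
    code = rep(codes[idx], ns),
    anchored = rep(anch[idx], ns),
    read_id = read_id,
    w = rep(w[idx], ns)
  )
  ci <- idx[-length(idx)]
  ci <- ci[(ci + 1) %in% idx]  # both k-mers of the transition present
  trans <- if (length(ci) > 0) {
    tibble(
      pos = rep(starts, each = length(ci)) + rep(ci - 1, ns),
      from = rep(codes[ci], ns),
      to = rep(codes[ci + 1], ns)
    )
  } else NULL
  list(support = support, trans = trans)
}

#' Aggregate the nodes of a positional de Bruijn graph
#'
#' @param g An `sv_graph`.
#' @return Tibble with one row per node: `pos`, `code`, `kmer` weight
#'   (summed, integer), `anchored` (true iff any supporting read anchors all
#'   k bases), and `n_support`.
#' @export
pg_nodes <- function(g) {
  s <- g$support
  if (nrow(s) == 0) {
    return(tibble(pos = numeric(0), code = numeric(0), weight = numeric(0),
                  anchored = logical(0), n_support = integer(0)))
  }
  # base aggregation on run-length groups of the sorted table (hot path)
  o <- order(s$pos, s$code)
  pos <- s$pos[o]; code <- s$code[o]
  new_grp <- c(TRUE, pos[-1] != pos[-length(pos)] |
                 code[-1] != code[-length(code)])
  gid <- cumsum(new_grp)
  first <- which(new_grp)
  tibble(
    pos = pos[first],
    code = code[first],
    weight = as.numeric(rowsum(s$w[o], gid, reorder = FALSE)),
    anchored = as.numeric(rowsum(as.numeric(s$anchored[o]), gid,
                                 reorder = FALSE)) > 0,
    n_support = as.integer(rowsum(rep(1L, length(gid)), gid,
                                  reorder = FALSE))
  )
}

# Edge list over an aggregated node tibble. Nodes are indexed by row; returns
# tibble(from_idx, to_idx).
pg_edges <- function(nodes, k) {
  if (nrow(nodes) == 0) return(tibble(from_idx = integer(0), to_idx = integer(0)))
  nd <- nodes %>% mutate(.idx = row_number(),
                         .suf = kmer_suffix(.data$code, k),
                         .pre = kmer_prefix(.data$code))
  inner_join(
    nd %>% select(from_idx = ".idx", pos_x = "pos", key = ".suf"),
    nd %>% mutate(pos_x = .data$pos - 1) %>%
      select(to_idx = ".idx", "pos_x", key = ".pre"),
    by = c("pos_x", "key"),
    relationship = "many-to-many"
  ) %>% select("from_idx", "to_idx")
}

# Deduplicated supported-transition table as edge indices over `nodes`.
pg_supported_edges <- function(g, nodes) {
  ed <- pg_edges(nodes, g$k)
  if (nrow(ed) == 0 || nrow(g$trans) == 0) {
    return(ed[0, ])
  }
  keys <- tibble(pos = nodes$pos[ed$from_idx],
                 from = nodes$code[ed$from_idx],
                 to = nodes$code[ed$to_idx])
  ok <- vctrs::vec_in(keys, g$trans[, c("pos", "from", "to")])
  ed[ok, ]
}

#' Remove reads from a positional de Bruijn graph
#'
#' Deletes every support contribution and supported transition of the given
#' reads; nodes whose support becomes empty vanish.
#'
#' @param g An `sv_graph`.
#' @param read_ids Character vector of read identifiers.
#' @return The updated graph.
#' @export
pg_remove_reads <- function(g, read_ids) {
  keep <- !(g$support$read_id %in% read_ids)
  removed <- g$support[!keep, ]
  g$support <- g$support[keep, ]
  if (nrow(removed) > 0 && nrow(g$trans) > 0) {
    # drop transitions whose endpoints no longer exist
    live <- distinct(g$support[, c("pos", "code")])
    keep_tr <- vctrs::vec_in(
      tibble(pos = g$trans$pos, code = g$trans$from), live) &
      vctrs::vec_in(
        tibble(pos = g$trans$pos + 1, code = g$trans$to), live)
    g$trans <- g$trans[keep_tr, ]
  }
  g
}

#' Total weight of a graph
#' @param g An `sv_graph`.
#' @return Sum of all node weights.
#' @export
pg_total_weight <- function(g) sum(g$support$w)

# ---- compression -------------------------------------------------------------

#' Compress a positional graph into path nodes
#'
#' Branchless chains (every interior node has a single predecessor and a
#' single successor, and a uniform anchored flag) are compressed into path
#' nodes `(start, end, (kmer_1, weight_1, ..., kmer_n, weight_n), anchored)`;
#' chains with identical k-mer/weight content at adjacent start positions are
#' further interval-compressed, `start`..`end` giving the run of start
#' positions. [pg_expand()] recovers the original node multiset exactly.
#'
#' @param g An `sv_graph`.
#' @return Tibble of path nodes with list columns `codes` and `weights`.
#' @export
pg_compress <- function(g) {
  nodes <- pg_nodes(g)
  k <- g$k
  if (nrow(nodes) == 0) {
    return(tibble(start = numeric(0), end = numeric(0), codes = list(),
                  weights = list(), anchored = logical(0)))
  }
  ed <- pg_edges(nodes, k)
  indeg <- tabulate(ed$to_idx, nrow(nodes))
  outdeg <- tabulate(ed$from_idx, nrow(nodes))
  nxt <- rep(NA_integer_, nrow(nodes))
  one_out <- which(outdeg == 1)
  succ <- ed$to_idx[match(one_out, ed$from_idx)]
  # chain link only when successor is unique in both directions and anchored
  # status matches
  ok <- indeg[succ] == 1 & nodes$anchored[succ] == nodes$anchored[one_out]
  nxt[one_out[ok]] <- succ[ok]
  is_target <- rep(FALSE, nrow(nodes))
  is_target[nxt[!is.na(nxt)]] <- TRUE
  starts <- which(!is_target)
  chains <- lapply(starts, function(s) {
    path <- s
    while (!is.na(nxt[path[length(path)]])) path <- c(path, nxt[path[length(path)]])
    path
  })
  ch <- tibble(
    start = map_dbl(chains, ~ nodes$pos[.x[1]]),
    codes = map(chains, ~ nodes$code[.x]),
    weights = map(chains, ~ nodes$weight[.x]),
    anchored = map_lgl(chains, ~ nodes$anchored[.x[1]])
  )
  # interval compression: identical chains at consecutive start positions
  ch$key <- map_chr(seq_len(nrow(ch)), function(i) {
    paste(paste(ch$codes[[i]], collapse = ","),
          paste(ch$weights[[i]], collapse = ","), ch$anchored[i], sep = "|")
  })
  ch %>%
    arrange(.data$key, .data$start) %>%
    group_by(.data$key) %>%
    mutate(run = cumsum(c(1, diff(.data$start) != 1))) %>%
    group_by(.data$key, .data$run) %>%
    summarise(end = max(.data$start), start = min(.data$start),
              codes = .data$codes[1], weights = .data$weights[1],
              anchored = .data$anchored[1], .groups = "drop") %>%
    select("start", "end", "codes", "weights", "anchored") %>%
    arrange(.data$start, map_dbl(.data$codes, 1))
}

#' Expand path nodes back to positional k-mer nodes
#'
#' @param pn Path-node tibble from [pg_compress()].
#' @return Node tibble (`pos`, `code`, `weight`, `anchored`), one row per
#'   node, with weights summed over coinciding expansions.
#' @export
pg_expand <- function(pn) {
  if (nrow(pn) == 0) {
    return(tibble(pos = numeric(0), code = numeric(0), weight = numeric(0),
                  anchored = logical(0)))
  }
  rows <- purrr::pmap(pn, function(start, end, codes, weights, anchored, ...) {
    offs <- seq_along(codes) - 1
    tibble(
      pos = rep(start:end, each = length(codes)) + rep(offs, end - start + 1),
      code = rep(codes, end - start + 1),
      weight = rep(weights, end - start + 1),
      anchored = anchored
    )
  })
  bind_rows(rows) %>%
    group_by(.data$pos, .data$code) %>%
    summarise(weight = sum(.data$weight), anchored = any(.data$anchored),
              .groups = "drop") %>%
    arrange(.data$pos, .data$code)
}

# ---- text dump / load --------------------------------------------------------

#' Write a graph to a tab-separated text file
#'
#' One row per (node, supporting read) contribution with columns
#' `position`, `kmer`, `weight`, `anchored`, `support`; lossless for
#' debugging and fixtures.
#'
#' @param g An `sv_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
pg_write_tsv <- function(g, path) {
  out <- g$support %>%
    mutate(kmer = kmer_string(.data$code, g$k)) %>%
    select(position = "pos", "kmer", weight = "w", "anchored",
           support = "read_id")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a graph from the tab-separated dump format
#' @param path File written by [pg_write_tsv()].
#' @param k K-mer size (taken from the k-mer column width if omitted).
#' @param direction Graph direction.
#' @return An `sv_graph`. Read-supported transitions are reconstructed from
#'   adjacent same-read k-mers.
#' @export
pg_read_tsv <- function(path, k = NULL, direction = "forward") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "character", "numeric",
                                         "logical", "character"))
  if (is.null(k)) k <- nchar(df$kmer[1])
  g <- pg_new(k, direction)
  g$support <- tibble(
    pos = df$position,
    code = vapply(df$kmer, function(s) kmer_codes(s, k), numeric(1)),
    anchored = df$anchored, read_id = df$support, w = df$weight
  )
  tr <- g$support %>%
    arrange(.data$read_id, .data$pos) %>%
    group_by(.data$read_id) %>%
    mutate(nxt_pos = lead(.data$pos), nxt_code = lead(.data$code)) %>%
    ungroup() %>%
    filter(!is.na(.data$nxt_pos), .data$nxt_pos == .data$pos + 1,
           kmer_suffix(.data$code, k) == kmer_prefix(.data$nxt_code))
  g$trans <- tr %>% select(pos = "pos", from = "code", to = "nxt_code")
  g
}
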