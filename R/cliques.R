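# Variant calling by maximal-clique enumeration.
#
# Each piece of breakpoint evidence is the tuple (s_l, e_l, s_h, e_h, d_l,
# d_h, w): an axis-aligned rectangle of supported breakpoint locations plus a
# Phred weight. Within each (chrom pair, d_l, d_h) directional subset,
# mutually consistent evidence corresponds to pairwise-overlapping
# rectangles; candidate variants are the maximal cliques of this rectangle
# graph, enumerated by an in-order interval sweep on each axis. A second,
# greedy pass assigns every piece of evidence to the highest-scoring variant
# it supports, so evidence weight is counted exactly once.

# maximal cliques of a closed-interval graph via a single in-order sweep;
# returns list of integer index vectors
interval_cliques <- function(s, e) {
  n <- length(s)
  if (n == 0) return(list())
  ev <- tibble(
    pos = c(s, e),
    type = rep(c(0L, 1L), each = n),  # 0 start, 1 end
    id = rep(seq_len(n), 2)
  ) %>% arrange(.data$pos, .data$type)
  active <- logical(n)
  grown <- FALSE
  out <- list()
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == 0L) {
      active[ev$id[i]] <- TRUE
      grown <- TRUE
    } else {
      if (grown) {
        out[[length(out) + 1]] <- which(active)
        grown <- FALSE
      }
      active[ev$id[i]] <- FALSE
    }
  }
  out
}

# maximal cliques of a rectangle graph: x-axis sweep, then y-axis sweep
# within each x-clique, then removal of dominated candidates
rectangle_cliques <- function(s_l, e_l, s_h, e_h) {
  xc <- interval_cliques(s_l, e_l)
  cand <- list()
  for (cx in xc) {
    yc <- interval_cliques(s_h[cx], e_h[cx])
    for (cy in yc) cand[[length(cand) + 1]] <- sort(cx[cy])
  }
  cand <- unique(cand)
  if (length(cand) <= 1) return(cand)
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (i != j && keep[i] && length(cand[[i]]) < length(cand[[j]]) &&
          all(cand[[i]] %in% cand[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cand[keep]
}

#' Enumerate maximal breakpoint-evidence cliques
#'
#' @param evidence Breakpoint-evidence tibble with columns `chrom_l`, `s_l`,
#'   `e_l`, `dir_l`, `chrom_h`, `s_h`, `e_h`, `dir_h`, `w` (and any id
#'   columns, carried through `members`).
#' @return Tibble of candidate variants: the directional subset, the clique
#'   interval (intersection of member rectangles), provisional `weight`
#'   (summed member weights) and a `members` list column of evidence row
#'   indices into `evidence`.
#' @export
enumerate_maximal_cliques <- function(evidence) {
  empty <- tibble(chrom_l = character(0), start_l = numeric(0),
                  end_l = numeric(0), dir_l = character(0),
                  chrom_h = character(0), start_h = numeric(0),
                  end_h = numeric(0), dir_h = character(0),
                  weight = numeric(0), members = list())
  if (nrow(evidence) == 0) return(empty)
  ev <- evidence %>% mutate(.row = row_number())
  groups <- ev %>%
    filter(!is.na(.data$chrom_h)) %>%
    group_by(.data$chrom_l, .data$chrom_h, .data$dir_l, .data$dir_h)
  out <- dplyr::group_map(groups, function(g, key) {
    cl <- rectangle_cliques(g$s_l, g$e_l, g$s_h, g$e_h)
    rows <- lapply(cl, function(idx) {
      tibble(
        chrom_l = key$chrom_l, dir_l = key$dir_l,
        chrom_h = key$chrom_h, dir_h = key$dir_h,
        start_l = max(g$s_l[idx]), end_l = min(g$e_l[idx]),
        start_h = max(g$s_h[idx]), end_h = min(g$e_h[idx]),
        weight = sum(g$w[idx]),
        members = list(g$.row[idx])
      )
    })
    bind_rows(rows)
  })
  res <- bind_rows(empty, bind_rows(out))
  res %>% arrange(.data$chrom_l, .data$start_l, .data$chrom_h, .data$start_h)
}

#' Greedily assign evidence to its highest-scoring variant
#'
#' Each evidence item supports possibly many overlapping cliques; it is
#' assigned to the clique with the greatest provisional weight (ties broken
#' toward the genomically first variant). Variant quality is recomputed from
#' assigned evidence only and unsupported variants are dropped, so the summed
#' quality over all variants equals the summed weight of assigned evidence.
#'
#' @param cliques Output of [enumerate_maximal_cliques()].
#' @param evidence The breakpoint-evidence tibble passed to it.
#' @return `cliques` with `qual` (assigned weight), pruned `members`, and
#'   zero-evidence variants removed.
#' @export
greedy_assign <- function(cliques, evidence) {
  if (nrow(cliques) == 0) {
    return(cliques %>% mutate(qual = numeric(0)))
  }
  # genomic order for tie-breaking (cliques are already sorted)
  long <- cliques %>%
    mutate(.clique = row_number()) %>%
    select(".clique", "weight", "members") %>%
    tidyr::unnest_longer("members", values_to = ".row")
  pick <- long %>%
    group_by(.data$.row) %>%
    arrange(desc(.data$weight), .data$.clique, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  assigned <- pick %>%
    mutate(w = evidence$w[.data$.row]) %>%
    group_by(.data$.clique) %>%
    summarise(qual = sum(.data$w), members = list(.data$.row),
              .groups = "drop")
  out <- cliques %>%
    mutate(.clique = row_number()) %>%
    select(-"members", -"weight") %>%
    inner_join(assigned, by = ".clique") %>%
    select(-".clique")
  out
}
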