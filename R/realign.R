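# Contig realignment: break-end contigs are converted into breakpoint
# evidence by Smith-Waterman realignment of the anchored portion around its
# expected position, alignment of the unanchored residue to the genome, and
# recursive realignment of any remaining soft clip (compound rearrangements),
# limited to a depth of `max_depth`.

#' Smith-Waterman local alignment
#'
#' Affine-gap local alignment (a gap of length g costs
#' `gap_open + g * gap_extend`). Defaults are bwa-like: match +1,
#' mismatch -4, gap open -6, gap extend -1.
#'
#' @param query,ref Non-empty DNA strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return One-row tibble: `score`, `q_start`, `q_end`, `r_start`, `r_end`
#'   (1-based, 0 when nothing aligns), `cigar` (M/I/D over the aligned run).
#' @export
smith_waterman <- function(query, ref, match = 1, mismatch = -4,
                           gap_open = -6, gap_extend = -1) {
  if (!nzchar(query) || !nzchar(ref)) abort("empty query or reference")
  # penalties are signed scores in the interface, costs in the DP core
  res <- sw_align_cpp(query, ref, match, mismatch, abs(gap_open),
                      abs(gap_extend))
  as_tibble(res[c("score", "q_start", "q_end", "r_start", "r_end", "cigar")])
}

# mismatch count of query vs a same-length reference slice
count_mismatches <- function(a, b) {
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

#' Locate a query sequence on the reference
#'
#' Scans an anchor window with Smith-Waterman (when an anchor is supplied)
#' plus a genome-wide near-exact scan on both strands; falls back to
#' exhaustive per-chromosome Smith-Waterman on small references. The
#' mapping-quality equivalent is derived from the score gap between the best
#' and second-best non-overlapping hits (single hit: 60).
#'
#' @param query DNA string.
#' @param reference Named character vector of chromosome sequences.
#' @param anchor_chrom,anchor_pos Optional expected locus.
#' @param window Half-width of the anchor window (bp).
#' @param match,mismatch,gap_open,gap_extend Smith-Waterman scoring.
#' @param max_mismatch_frac Mismatch budget of the near-exact scan.
#' @return One-row tibble (`chrom`, `pos_start`, `pos_end`, `strand`,
#'   `score`, `mapq`, `q_start`, `q_end`) or `NULL` when nothing scores
#'   above half the maximum.
#' @export
sw_locate <- function(query, reference, anchor_chrom = NULL,
                      anchor_pos = NULL, window = 2000,
                      match = 1, mismatch = -4, gap_open = -6,
                      gap_extend = -1, max_mismatch_frac = 0.06) {
  L <- nchar(query)
  if (L == 0) return(NULL)
  hits <- list()
  add_hit <- function(chrom, pos_start, pos_end, strand, score, q_start, q_end) {
    hits[[length(hits) + 1]] <<- tibble(
      chrom = chrom, pos_start = pos_start, pos_end = pos_end,
      strand = strand, score = score, q_start = q_start, q_end = q_end)
  }
  sw_window <- function(chrom, lo, hi, strand) {
    lo <- max(1, lo); hi <- min(nchar(reference[chrom]), hi)
    if (hi - lo + 1 < 10) return()
    win <- substr(reference[chrom], lo, hi)
    q <- if (strand == "+") query else revcomp(query)
    a <- smith_waterman(q, win, match, mismatch, gap_open, gap_extend)
    if (a$score <= 0) return()
    qs <- a$q_start; qe <- a$q_end
    if (strand == "-") { qs <- L - a$q_end + 1; qe <- L - a$q_start + 1 }
    add_hit(chrom, lo + a$r_start - 1, lo + a$r_end - 1, strand, a$score,
            qs, qe)
  }
  if (!is.null(anchor_chrom) && !is.na(anchor_chrom)) {
    for (s in c("+", "-"))
      sw_window(anchor_chrom, anchor_pos - window, anchor_pos + window, s)
  }
  mm <- max(1L, floor(L * max_mismatch_frac))
  for (ch in names(reference)) {
    subj <- Biostrings::DNAString(reference[ch])
    for (s in c("+", "-")) {
      q <- if (s == "+") query else revcomp(query)
      m <- Biostrings::matchPattern(q, subj, max.mismatch = mm)
      if (length(m) == 0) next
      st <- Biostrings::start(m); en <- Biostrings::end(m)
      keep <- en - st + 1 == L  # reject edge-truncated hits
      st <- st[keep]; en <- en[keep]
      if (length(st) == 0) next
      nm <- count_mismatches(rep(q, length(st)),
                             substring(reference[ch], st, en))
      for (j in seq_along(st)) {
        add_hit(ch, st[j], en[j], s, (L - nm[j]) * match + nm[j] * mismatch,
                1L, L)
      }
    }
  }
  if (length(hits) == 0 && sum(nchar(reference)) <= 2e6) {
    for (ch in names(reference))
      for (s in c("+", "-")) sw_window(ch, 1, nchar(reference[ch]), s)
  }
  if (length(hits) == 0) return(NULL)
  h <- bind_rows(hits)
  # collapse near-duplicate hits (same chrom/strand within 10 bp)
  h <- h %>%
    arrange(desc(.data$score)) %>%
    mutate(cluster = NA_integer_)
  cl <- 0
  for (i in seq_len(nrow(h))) {
    if (!is.na(h$cluster[i])) next
    cl <- cl + 1
    same <- h$chrom == h$chrom[i] & h$strand == h$strand[i] &
      abs(h$pos_start - h$pos_start[i]) <= 10
    h$cluster[same & is.na(h$cluster)] <- cl
  }
  h <- h %>% group_by(.data$cluster) %>% slice(1) %>% ungroup() %>%
    arrange(desc(.data$score))
  best <- h[1, ]
  if (best$score < 0.5 * L * match) return(NULL)
  mapq <- if (nrow(h) == 1) 60
  else max(0, min(60, round(4 * (best$score - h$score[2]))))
  best %>% mutate(mapq = mapq) %>% select(-"cluster")
}

#' Build the default internal aligner over a reference
#'
#' @param reference Named character vector of chromosome sequences.
#' @param ... Passed to [sw_locate()].
#' @return `function(query, anchor_chrom = NULL, anchor_pos = NULL)`
#'   fulfilling the pluggable aligner contract.
#' @export
sw_genome_aligner <- function(reference, ...) {
  function(query, anchor_chrom = NULL, anchor_pos = NULL) {
    sw_locate(query, reference, anchor_chrom = anchor_chrom,
              anchor_pos = anchor_pos, ...)
  }
}

empty_breakpoints <- function() {
  tibble(contig_id = character(0),
         chrom_l = character(0), s_l = numeric(0), e_l = numeric(0),
         dir_l = character(0),
         chrom_h = character(0), s_h = numeric(0), e_h = numeric(0),
         dir_h = character(0),
         untemplated = character(0), origin = character(0),
         realign_mapq = numeric(0), anchor_side = character(0))
}

canonical_bp_row <- function(contig_id, left, right, untemplated,
                             origin, realign_mapq, anchor_on_left) {
  flip <- (right$chrom < left$chrom) ||
    (right$chrom == left$chrom && right$pos < left$pos)
  if (flip) {
    tmp <- left; left <- right; right <- tmp
    if (nzchar(untemplated)) untemplated <- revcomp(untemplated)
    anchor_on_left <- !anchor_on_left
  }
  tibble(contig_id = contig_id,
         chrom_l = left$chrom, s_l = left$pos, e_l = left$pos,
         dir_l = left$dir,
         chrom_h = right$chrom, s_h = right$pos, e_h = right$pos,
         dir_h = right$dir,
         untemplated = untemplated, origin = origin,
         realign_mapq = realign_mapq,
         anchor_side = if (anchor_on_left) "l" else "h")
}

#' Realign a break-end contig into breakpoint evidence
#'
#' Anchored contigs are Smith-Waterman realigned around the expected
#' position; a contig that fully aligns is kept only if the alignment
#' contains an indel (indel-spanning assembly), otherwise discarded as a
#' false positive. The unanchored residue is located with the pluggable
#' aligner and any remaining soft clip is realigned recursively up to
#' `max_depth`, yielding one breakpoint per junction spanned by the
#' assembly. If the residue cannot be located, the contig becomes
#' single-break-end evidence (no partner).
#'
#' @param contig One-row contig tibble from [assemble_evidence()] (fields
#'   `contig_id`, `chrom`, `direction`, `anchor_start`, `anchor_end`, `seq`,
#'   `anchor_nodes`).
#' @param reference Named character vector of chromosome sequences.
#' @param metrics Library metrics (for the realignment window size).
#' @param aligner Pluggable aligner (default [sw_genome_aligner()]).
#' @param max_depth Maximum recursive realignment depth (default 4).
#' @param min_mapq Minimum residue mapping quality (default 10).
#' @param min_residue Minimum residue length worth aligning (default 18 bp).
#' @return Breakpoint-evidence tibble (possibly empty); `chrom_h = NA` marks
#'   single-break-end rows.
#' @export
realign_contig <- function(contig, reference, metrics, aligner = NULL,
                           max_depth = 4, min_mapq = 10, min_residue = 18) {
  if (is.null(aligner)) aligner <- sw_genome_aligner(reference)
  seq <- contig$seq
  L <- nchar(seq)
  out <- empty_breakpoints()
  if (contig$anchor_nodes > 0) {
    win <- (if (!is.null(metrics$concordant_hi) &&
                !is.na(metrics$concordant_hi))
      metrics$concordant_hi else 1000) + L
    lo <- max(1, contig$anchor_start - win)
    hi <- min(nchar(reference[contig$chrom]), contig$anchor_end + win)
    window <- substr(reference[contig$chrom], lo, hi)
    a <- smith_waterman(seq, window)
    if (a$score <= 0) return(out)
    full <- a$q_start == 1 && a$q_end == L
    if (full) {
      if (!grepl("[ID]", a$cigar)) return(out)  # matches reference: artifact
      return(indel_breakpoints(contig, a, lo))
    }
    # align only the anchored segment so the junction sits at its boundary;
    # aligning the whole contig can latch onto the (longer) unanchored side
    # or creep across junction microhomology
    alen <- min(L - 1, contig$anchor_end - contig$anchor_start + 1)
    if (contig$direction == "+") {
      a2 <- smith_waterman(substr(seq, 1, alen), window)
      if (a2$score <= 0) return(out)
      residue <- substr(seq, a2$q_end + 1, L)
      left <- list(chrom = contig$chrom, pos = lo + a2$r_end - 1, dir = "+")
    } else {
      off <- L - alen
      a2 <- smith_waterman(substr(seq, off + 1, L), window)
      if (a2$score <= 0) return(out)
      residue <- substr(seq, 1, off + a2$q_start - 1)
      left <- list(chrom = contig$chrom, pos = lo + a2$r_start - 1, dir = "-")
    }
    walk_junction_chain(contig$contig_id, left, residue, contig$direction,
                        aligner, max_depth, min_mapq, min_residue)
  } else {
    # unanchored (read-pair only) contig: locate the whole sequence; treat
    # the best hit as one side and walk the remainder
    hit <- aligner(seq, NA, NA)
    if (is.null(hit) || hit$mapq < min_mapq) return(out)
    if (hit$strand == "+") {
      left <- list(chrom = hit$chrom, pos = hit$pos_end, dir = "+")
      residue <- substr(seq, hit$q_end + 1, L)
      dirn <- "+"
    } else {
      left <- list(chrom = hit$chrom, pos = hit$pos_start, dir = "-")
      residue <- substr(seq, 1, hit$q_start - 1)
      dirn <- "+"
      residue <- revcomp(residue)  # continue in derived orientation
    }
    walk_junction_chain(contig$contig_id, left, residue, dirn, aligner,
                        max_depth, min_mapq, min_residue)
  }
}

# indel-spanning fully aligned assembly: one breakpoint per I/D operation
indel_breakpoints <- function(contig, a, win_lo) {
  ops <- cigar_ops(a$cigar)[[1]]
  refoff <- 0; qoff <- a$q_start - 1
  rows <- list()
  for (j in seq_along(ops$op)) {
    op <- ops$op[j]; ln <- ops$len[j]
    if (op %in% c("I", "D")) {
      p <- win_lo + a$r_start - 1 + refoff - 1
      left <- list(chrom = contig$chrom, pos = p, dir = "+")
      right <- list(chrom = contig$chrom,
                    pos = if (op == "D") p + ln + 1 else p + 1, dir = "-")
      unt <- if (op == "I") substr(contig$seq, qoff + 1, qoff + ln) else ""
      rows[[length(rows) + 1]] <- canonical_bp_row(
        contig$contig_id, left, right, unt, "ASSEMBLY", 60,
        anchor_on_left = contig$direction == "+")
    }
    if (op %in% c("M", "D")) refoff <- refoff + ln
    if (op %in% c("M", "I")) qoff <- qoff + ln
  }
  bind_rows(empty_breakpoints(), bind_rows(rows))
}

# Walk the junction chain of a contig: `left` is the break-end of the last
# aligned segment, `residue` the remaining bases adjacent to it. For
# direction "+" the junction-adjacent residue end is its start; for "-" its
# end.
walk_junction_chain <- function(contig_id, left, residue, direction,
                                aligner, max_depth, min_mapq, min_residue,
                                depth = 1, anchor_on_left = TRUE) {
  out <- empty_breakpoints()
  if (depth > max_depth) return(out)
  if (nchar(residue) < min_residue) return(out)
  # locate the junction-adjacent segment: if the best alignment of the
  # residue leaves a long unaligned stretch on the junction side (a compound
  # rearrangement), realign that stretch alone until the hit abuts the
  # junction
  locate_adjacent <- function(residue) {
    sub <- residue
    cut <- 0   # bases trimmed from the far (non-junction) side
    repeat {
      hit <- tryCatch(aligner(sub, NA, NA), error = function(e) NULL)
      if (is.null(hit)) return(NULL)
      gap <- if (direction == "+") hit$q_start - 1
      else nchar(sub) - hit$q_end
      if (gap < min_residue) {
        if (direction != "+") {
          hit$q_start <- hit$q_start + cut
          hit$q_end <- hit$q_end + cut
        }
        return(hit)
      }
      if (direction == "+") {
        sub <- substr(sub, 1, hit$q_start - 1)
      } else {
        cut <- cut + hit$q_end
        sub <- substr(residue, cut + 1, nchar(residue))
      }
    }
  }
  hit <- locate_adjacent(residue)
  if (is.null(hit) || hit$mapq < min_mapq) {
    # single break-end: partner unknown
    return(bind_rows(out, tibble(
      contig_id = contig_id,
      chrom_l = left$chrom, s_l = left$pos, e_l = left$pos, dir_l = left$dir,
      chrom_h = NA_character_, s_h = NA_real_, e_h = NA_real_,
      dir_h = NA_character_,
      untemplated = residue, origin = "ASSEMBLY",
      realign_mapq = 0, anchor_side = "l")))
  }
  if (direction == "+") {
    if (hit$strand == "+") {
      partner <- list(chrom = hit$chrom, pos = hit$pos_start, dir = "-")
      nxt_left <- list(chrom = hit$chrom, pos = hit$pos_end, dir = "+")
    } else {
      partner <- list(chrom = hit$chrom, pos = hit$pos_end, dir = "+")
      nxt_left <- list(chrom = hit$chrom, pos = hit$pos_start, dir = "-")
    }
    unt <- substr(residue, 1, hit$q_start - 1)
    nxt_res <- substr(residue, hit$q_end + 1, nchar(residue))
  } else {
    if (hit$strand == "+") {
      partner <- list(chrom = hit$chrom, pos = hit$pos_end, dir = "+")
      nxt_left <- list(chrom = hit$chrom, pos = hit$pos_start, dir = "-")
    } else {
      partner <- list(chrom = hit$chrom, pos = hit$pos_start, dir = "-")
      nxt_left <- list(chrom = hit$chrom, pos = hit$pos_end, dir = "+")
    }
    unt <- substr(residue, hit$q_end + 1, nchar(residue))
    nxt_res <- substr(residue, 1, hit$q_start - 1)
  }
  row <- canonical_bp_row(contig_id, left, partner, unt, "ASSEMBLY",
                          hit$mapq, anchor_on_left)
  rest <- walk_junction_chain(contig_id, nxt_left, nxt_res, direction,
                              aligner, max_depth, min_mapq, min_residue,
                              depth + 1, anchor_on_left = FALSE)
  bind_rows(out, row, rest)
}
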