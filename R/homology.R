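# Microhomology and inexact homology detection.
#
# Sequence shared by both sides of a breakpoint lets the junction slide:
# the call position is expanded from a single base to the homology interval,
# the nominal position is the interval centre (floored toward the lower
# coordinate for even lengths), and HOMSEQ/HOMLEN/CIPOS report it. Inexact
# homology (IHOMPOS) extends the interval by gapless Smith-Waterman-scored
# comparison (match +1, mismatch -4) of the breakpoint sequence against the
# reference up to `max_ihom_window` bp either side of the break-end.
# A junction with untemplated inserted bases has no positional ambiguity:
# homology length is zero.

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

# direction-aware accessors around a junction; i >= 1
side_accessors <- function(reference, chrom, pos, dir) {
  L <- nchar(reference[chrom])
  ref_at <- function(p) {
    ifelse(p >= 1 & p <= L, substr(reference[chrom], p, p), "")
  }
  if (dir == "+") {
    list(
      retained = function(i) ref_at(pos - i + 1),   # i-th base before junction
      beyond = function(i) ref_at(pos + i)          # i-th base past junction
    )
  } else {
    list(
      retained = function(i) comp_base(ref_at(pos + i - 1)),
      beyond = function(i) comp_base(ref_at(pos - i))
    )
  }
}

#' Exact and inexact homology of a breakpoint
#'
#' @param reference Named character vector of chromosome sequences.
#' @param chrom_l,pos_l,dir_l,chrom_h,pos_h,dir_h The two break-ends
#'   (genomically ordered).
#' @param untemplated Inserted sequence at the junction (l-first derived
#'   orientation); non-empty insertions resolve the ambiguity, so homology is
#'   zero.
#' @param max_window Maximum homology extension considered per side.
#' @return List: `homlen`, `homseq`, `lo`/`hi` (interval of valid `pos_l`),
#'   `lo_h`/`hi_h` (corresponding `pos_h` interval), `left`/`right`
#'   (extension in derived orientation), `ileft`/`iright` (inexact
#'   extensions, always >= the exact ones).
#' @export
junction_homology <- function(reference, chrom_l, pos_l, dir_l,
                              chrom_h, pos_h, dir_h, untemplated = "",
                              max_window = 300) {
  pos_l <- unname(pos_l); pos_h <- unname(pos_h)
  sl <- side_accessors(reference, chrom_l, pos_l, dir_l)
  sh <- side_accessors(reference, chrom_h, pos_h, dir_h)
  zero <- !is.na(untemplated) && nzchar(untemplated)
  # derived-orientation slide: right consumes l-side beyond vs h-side
  # retained-from-junction; left consumes l-side retained vs h-side beyond
  ext <- function(a, b) {
    i <- 0
    while (i < max_window) {
      x <- a(i + 1); y <- b(i + 1)
      if (x == "" || y == "" || is.na(x) || is.na(y) || x != y) break
      i <- i + 1
    }
    i
  }
  scored_ext <- function(a, b, from) {
    # continue past the exact boundary with SW-style scoring; the furthest
    # position attaining the running maximum is the inexact extent
    score <- from; best <- from; arg <- from
    i <- from
    while (i < max_window) {
      x <- a(i + 1); y <- b(i + 1)
      if (x == "" || y == "" || is.na(x) || is.na(y)) break
      score <- score + ifelse(x == y, 1, -4)
      i <- i + 1
      if (score > best) { best <- score; arg <- i }
      if (score < best - 12) break  # x-drop
    }
    arg
  }
  # the h side viewed in the l-first derived orientation is the complement of
  # its own side-first reading
  hcont <- function(i) comp_base(sh$retained(i))
  hprev <- function(i) comp_base(sh$beyond(i))
  right <- if (zero) 0 else ext(sl$beyond, hcont)
  left <- if (zero) 0 else ext(sl$retained, hprev)
  iright <- scored_ext(sl$beyond, hcont, right)
  ileft <- scored_ext(sl$retained, hprev, left)
  homlen <- left + right
  homseq <- if (homlen == 0) "" else paste(
    c(rev(vapply(seq_len(left), sl$retained, character(1))),
      vapply(seq_len(right), sl$beyond, character(1))), collapse = "")
  sgn_l <- if (dir_l == "+") 1 else -1
  sgn_h <- if (dir_h == "-") 1 else -1
  list(
    homlen = homlen, homseq = homseq,
    left = left, right = right, ileft = ileft, iright = iright,
    lo = pos_l - (if (sgn_l > 0) left else right),
    hi = pos_l + (if (sgn_l > 0) right else left),
    lo_h = min(pos_h + sgn_h * right, pos_h - sgn_h * left),
    hi_h = max(pos_h + sgn_h * right, pos_h - sgn_h * left)
  )
}

# Expand single-base breakpoint evidence to its microhomology interval so
# that evidence placed at opposite homology edges (a known aligner/assembly
# behaviour that would otherwise yield two separate calls for one event)
# lands in the same clique.
expand_exact_rows <- function(bps, reference) {
  idx <- which(bps$s_l == bps$e_l & bps$s_h == bps$e_h)
  # preserve the original single-base junction estimates: homology
  # annotation anchors at a real observed junction, not a clique corner
  bps$j_l <- NA_real_; bps$j_h <- NA_real_
  bps$j_l[idx] <- bps$s_l[idx]; bps$j_h[idx] <- bps$s_h[idx]
  for (i in idx) {
    r <- bps[i, ]
    if (!is.na(r$untemplated) && nzchar(r$untemplated)) next
    h <- tryCatch(
      junction_homology(reference, r$chrom_l, r$s_l, r$dir_l,
                        r$chrom_h, r$s_h, r$dir_h, ""),
      error = function(e) NULL)
    if (is.null(h) || h$homlen == 0) next
    bps$s_l[i] <- h$lo; bps$e_l[i] <- h$hi
    bps$s_h[i] <- h$lo_h; bps$e_h[i] <- h$hi_h
  }
  bps
}

#' Annotate calls with homology, CIPOS and untemplated sequence
#'
#' Calls with single-base junction resolution (split-read or assembly
#' support) get exact microhomology (`homlen`, `homseq`), the nominal
#' position recentred to the homology midpoint, `cipos_*` spanning the
#' homology interval, and `ihom_*` from inexact (mismatch-tolerant)
#' extension. Read-pair-only calls keep their evidence interval as `cipos_*`
#' with homology fields `NA`.
#'
#' @param calls Call tibble (from [greedy_assign()], with `untemplated`).
#' @param reference Named character vector of chromosome sequences.
#' @param max_ihom_window Inexact-homology search window (default 300 bp).
#' @return `calls` with `pos_l`, `pos_h`, `homlen`, `homseq`, `cipos_lo`,
#'   `cipos_hi`, `ihom_lo`, `ihom_hi` columns.
#' @export
annotate_homology <- function(calls, reference, max_ihom_window = 300) {
  n <- nrow(calls)
  add <- tibble(pos_l = numeric(n), pos_h = numeric(n),
                homlen = NA_real_, homseq = NA_character_,
                cipos_lo = numeric(n), cipos_hi = numeric(n),
                ihom_lo = NA_real_, ihom_hi = NA_real_)
  for (i in seq_len(n)) {
    cl <- calls[i, ]
    # single-base junction resolution: any split-read or assembly member
    # (evidence rectangles are homology-expanded, so interval width alone
    # does not distinguish exact from read-pair-only calls)
    exact <- if (all(c("n_sr", "n_as") %in% names(cl))) {
      (cl$n_sr + cl$n_as) > 0
    } else {
      cl$start_l == cl$end_l && cl$start_h == cl$end_h
    }
    if (!exact) {
      # interval-resolution call: centre nominal position, CIPOS = interval
      add$pos_l[i] <- floor((cl$start_l + cl$end_l) / 2)
      add$pos_h[i] <- floor((cl$start_h + cl$end_h) / 2)
      add$cipos_lo[i] <- cl$start_l - add$pos_l[i]
      add$cipos_hi[i] <- cl$end_l - add$pos_l[i]
      next
    }
    unt <- if ("untemplated" %in% names(cl)) cl$untemplated else ""
    if (is.na(unt)) unt <- ""
    sgn_l <- if (cl$dir_l == "+") 1 else -1
    sgn_h <- if (cl$dir_h == "-") 1 else -1
    # anchor at the observed junction of the call's strongest exact
    # evidence when available (a clique corner can sit off the homology
    # diagonal when read-pair intervals trim the intersection)
    if (all(c("junc_l", "junc_h") %in% names(cl)) && !is.na(cl$junc_l)) {
      p_l0 <- cl$junc_l; p_h0 <- cl$junc_h
    } else {
      p_l0 <- if (sgn_l > 0) cl$start_l else cl$end_l
      p_h0 <- if (sgn_h > 0) cl$start_h else cl$end_h
    }
    h <- junction_homology(reference, cl$chrom_l, p_l0, cl$dir_l,
                           cl$chrom_h, p_h0, cl$dir_h, unt,
                           max_window = max_ihom_window)
    # nominal position: centre of the homology interval, floored
    nom <- h$lo + floor((h$hi - h$lo) / 2)
    shift <- nom - p_l0                 # slide applied to the lower side
    # the same derived-orientation slide moves the higher side accordingly
    nom_h <- p_h0 + sgn_h * sgn_l * shift
    add$pos_l[i] <- nom
    add$pos_h[i] <- nom_h
    add$homlen[i] <- h$homlen
    add$homseq[i] <- h$homseq
    add$cipos_lo[i] <- h$lo - nom
    add$cipos_hi[i] <- h$hi - nom
    extra_l <- h$ileft - h$left
    extra_r <- h$iright - h$right
    add$ihom_lo[i] <- (h$lo - nom) - (if (sgn_l > 0) extra_l else extra_r)
    add$ihom_hi[i] <- (h$hi - nom) + (if (sgn_l > 0) extra_r else extra_l)
  }
  bind_cols(calls, add)
}

#' Classify call confidence
#'
#' `HIGH` requires quality at least `qual_threshold` and assembly support at
#' both break-ends; everything else is `LOW` (and retained, for analyses that
#' need high sensitivity).
#'
#' @param calls Call tibble with `qual` and `assembly_sides` columns.
#' @param qual_threshold Minimum quality for a high-confidence call
#'   (default 500).
#' @return `calls` with a `confidence` column.
#' @export
classify_confidence <- function(calls, qual_threshold = 500) {
  calls %>%
    mutate(confidence = if_else(
      .data$qual >= qual_threshold & .data$assembly_sides == 2,
      "HIGH", "LOW"))
}
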