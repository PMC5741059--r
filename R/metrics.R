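# Library metrics: an initial parse of the alignments collects, per input
# file, the empirical fragment-size, soft-clip-length and indel-length
# distributions, read/pair counts, concordant fragment-size bounds at the
# configured percentile, the chimera rate p_d (fragments more than 10 median
# absolute deviations from the median) and the one-end-anchor rate p_u.

#' Read alignments into a tibble
#'
#' Accepts a coordinate-sorted SAM or BAM path (SAM is converted in a
#' temporary directory via Rsamtools) or an alignment tibble, and returns the
#' standard columns used by the extraction stage.
#'
#' @param x SAM/BAM path or alignment tibble.
#' @return Tibble with `qname`, `flag`, `chrom`, `pos`, `mapq`, `cigar`,
#'   `mchrom`, `mpos`, `seq`, `qual`.
#' @export
read_alignments <- function(x) {
  if (is.data.frame(x)) return(as_tibble(x))
  stopifnot(is.character(x), length(x) == 1L, file.exists(x))
  bam <- x
  if (grepl("\\.sam$", x, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(x, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble(
    qname = b$qname, flag = b$flag,
    chrom = as.character(b$rname), pos = b$pos,
    mapq = as.integer(b$mapq), cigar = b$cigar,
    mchrom = as.character(b$mrnm), mpos = b$mpos,
    seq = as.character(b$seq), qual = as.character(b$qual)
  )
}

flag_bit <- function(flag, bit) bitwAnd(flag, bit) > 0L

# primary, non-duplicate records used for metrics and extraction
primary_records <- function(aln) {
  aln %>% filter(!flag_bit(.data$flag, 0x100), !flag_bit(.data$flag, 0x800),
                 !flag_bit(.data$flag, 0x400))
}

# per-pair table: one row per qname with both primary records
pair_table <- function(aln) {
  pr <- primary_records(aln) %>% filter(flag_bit(.data$flag, 0x1))
  pr <- pr %>%
    mutate(is_r1 = flag_bit(.data$flag, 0x40),
           mapped = !flag_bit(.data$flag, 0x4),
           strand = if_else(flag_bit(.data$flag, 0x10), "-", "+"),
           ref_end = .data$pos + cigar_ref_width(.data$cigar) - 1)
  r1 <- pr %>% filter(.data$is_r1)
  r2 <- pr %>% filter(!.data$is_r1)
  inner_join(r1, r2, by = "qname", suffix = c("_1", "_2"))
}

# inferred fragment size: outermost-base span, recomputed from the two
# alignments (TLEN is not trusted)
pair_ifs <- function(pt) {
  same <- pt$mapped_1 & pt$mapped_2 & pt$chrom_1 == pt$chrom_2
  ifelse(same,
         pmax(pt$ref_end_1, pt$ref_end_2) - pmin(pt$pos_1, pt$pos_2) + 1,
         Inf)
}

# forward-reverse inward-facing orientation?
pair_proper_orientation <- function(pt) {
  same <- pt$mapped_1 & pt$mapped_2 & pt$chrom_1 == pt$chrom_2
  lo_strand <- ifelse(pt$pos_1 <= pt$pos_2, pt$strand_1, pt$strand_2)
  hi_strand <- ifelse(pt$pos_1 <= pt$pos_2, pt$strand_2, pt$strand_1)
  same & ((lo_strand == "+" & hi_strand == "-") |
            (pt$pos_1 == pt$pos_2 & pt$strand_1 != pt$strand_2))
}

empirical_dist <- function(x) {
  if (length(x) == 0) return(tibble(value = numeric(0), prob = numeric(0)))
  tb <- table(x)
  tibble(value = as.numeric(names(tb)), prob = as.numeric(tb) / length(x))
}

# per-read largest clip / indel-op length, zero when absent, so the tail
# mass P(L >= l) is the per-read rate of carrying such an element
per_read_max_op <- function(cigar, ops_wanted) {
  ops <- cigar_ops(cigar)
  vapply(ops, function(x) {
    v <- x$len[x$op %in% ops_wanted]
    if (length(v) == 0) 0 else max(v)
  }, numeric(1))
}

#' Collect library metrics from an alignment file
#'
#' @param x Coordinate-sorted SAM/BAM path or alignment tibble.
#' @param concordance_percentile Fraction of training pairs regarded as
#'   concordant; the bounds are the `(1-p)/2` and `1-(1-p)/2` empirical order
#'   statistics of the inferred fragment sizes (default 0.995).
#' @param library_id Library name (defaults to the file basename).
#' @param mapq_cap Mapping quality substituted for the SAM "unavailable"
#'   value 255 (default 60).
#' @return An `sv_metrics` object: empirical distributions
#'   (`fragment_size_dist`, `softclip_len_dist`, `insertion_len_dist`,
#'   `deletion_len_dist`, each a tibble of `value`/`prob`), `read_counts`,
#'   `max_read_length`, `max_mapped_read_length`, `concordant_lo`/`hi`,
#'   `p_d`, `p_u`, and observation counts used for tail-mass floors.
#' @export
collect_metrics <- function(x, concordance_percentile = 0.995,
                            library_id = NULL, mapq_cap = 60) {
  if (concordance_percentile <= 0.5 || concordance_percentile >= 1)
    abort("concordance_percentile must be in (0.5, 1)")
  if (is.null(library_id)) {
    library_id <- if (is.character(x)) basename(x) else "lib1"
  }
  aln <- read_alignments(x)
  if (nrow(aln) == 0) abort("no reads")
  pr <- primary_records(aln)
  mapped <- pr %>% filter(!flag_bit(.data$flag, 0x4))
  counts <- list(
    total_reads = nrow(pr),
    mapped_reads = nrow(mapped),
    unmapped_reads = nrow(pr) - nrow(mapped)
  )
  pt <- pair_table(aln)
  counts$total_pairs <- nrow(pt)
  counts$pairs_both_mapped <- sum(pt$mapped_1 & pt$mapped_2)
  counts$pairs_one_mapped <- sum(xor(pt$mapped_1, pt$mapped_2))
  counts$pairs_both_unmapped <- sum(!pt$mapped_1 & !pt$mapped_2)

  sc <- per_read_max_op(mapped$cigar, "S")
  ins <- per_read_max_op(mapped$cigar, "I")
  del <- per_read_max_op(mapped$cigar, "D")

  proper <- pair_proper_orientation(pt)
  ifs <- pair_ifs(pt)[proper]
  ifs <- ifs[is.finite(ifs)]
  pairs_available <- length(ifs) > 0
  if (pairs_available) {
    alpha <- (1 - concordance_percentile) / 2
    qs <- stats::quantile(ifs, c(alpha, 1 - alpha), type = 1, names = FALSE)
    med <- median(ifs)
    mad_raw <- stats::mad(ifs, constant = 1)
    p_d <- mean(abs(ifs - med) > 10 * mad_raw)
  } else {
    qs <- c(NA_real_, NA_real_); p_d <- NA_real_
    if (counts$total_pairs > 0)
      warn(sprintf("library %s: no mapped proper pairs; pair-based evidence disabled",
                   library_id))
  }
  p_u <- if (counts$total_pairs > 0)
    counts$pairs_one_mapped / counts$total_pairs else 0

  structure(list(
    library_id = library_id,
    fragment_size_dist = empirical_dist(ifs),
    softclip_len_dist = empirical_dist(sc),
    insertion_len_dist = empirical_dist(ins),
    deletion_len_dist = empirical_dist(del),
    read_counts = counts,
    max_read_length = if (nrow(pr) > 0) max(nchar(pr$seq)) else 0L,
    max_mapped_read_length = if (nrow(mapped) > 0) max(nchar(mapped$seq)) else 0L,
    concordant_lo = qs[1], concordant_hi = qs[2],
    p_d = p_d, p_u = p_u,
    n_fragments = length(ifs),
    n_softclips = length(sc), n_insertions = length(ins),
    n_deletions = length(del),
    pairs_available = pairs_available,
    concordance_percentile = concordance_percentile,
    mapq_cap = mapq_cap
  ), class = "sv_metrics")
}

#' @export
print.sv_metrics <- function(x, ...) {
  cat("<library metrics:", x$library_id, ">\n")
  cat(sprintf("  reads: %d (%d mapped), pairs: %d\n",
              x$read_counts$total_reads, x$read_counts$mapped_reads,
              x$read_counts$total_pairs))
  if (x$pairs_available) {
    cat(sprintf("  fragment size: median %g, concordant [%g, %g]\n",
                weighted_median(x$fragment_size_dist$value,
                                x$fragment_size_dist$prob),
                x$concordant_lo, x$concordant_hi))
  }
  cat(sprintf("  p_d = %.3g, p_u = %.3g\n", x$p_d, x$p_u))
  invisible(x)
}
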