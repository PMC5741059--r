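# Extraction of SV-supporting reads.
#
# Reads partially aligned to the reference (soft clips, indels) and read
# pairs with unexpected fragment size, wrong orientation, different
# chromosomes or exactly one mapped read are extracted as evidence; fully
# concordant pairs and pairs with both reads unmapped are not. Duplicate and
# secondary/supplementary records are dropped, as are soft clips shorter
# than `min_clip` bases or averaging below `min_clip_baseq` base quality
# (adapter / quality artifacts).

#' Classify a single read
#'
#' Returns the (possibly empty, non-exclusive) set of evidence kinds the read
#' provides: `SOFT_CLIP`, `INDEL`, `DISCORDANT_PAIR`, `ONE_END_ANCHOR`.
#' Pairs with both reads unmapped yield nothing.
#'
#' @param read List/row with `mapped`, `cigar`, `paired`.
#' @param mate_info List with `mapped`, `same_chrom`, `proper_orientation`,
#'   `ifs`; `NULL` for unpaired reads.
#' @param metrics Library metrics ([collect_metrics()]); needed for the
#'   fragment-size bounds (pair-based classes are skipped when pair metrics
#'   are unavailable).
#' @return Character vector of evidence kinds.
#' @export
classify_read <- function(read, mate_info = NULL, metrics = NULL) {
  kinds <- character(0)
  mate_mapped <- !is.null(mate_info) && isTRUE(mate_info$mapped)
  if (!isTRUE(read$mapped) && !mate_mapped) return(kinds)
  if (isTRUE(read$mapped)) {
    ops <- cigar_ops(read$cigar)[[1]]
    if (any(ops$op == "S")) kinds <- c(kinds, "SOFT_CLIP")
    if (any(ops$op %in% c("I", "D"))) kinds <- c(kinds, "INDEL")
  }
  if (isTRUE(read$paired) && !is.null(mate_info)) {
    if (isTRUE(read$mapped) && mate_mapped) {
      size_ok <- if (!is.null(metrics) && isTRUE(metrics$pairs_available)) {
        !is.na(mate_info$ifs) && is.finite(mate_info$ifs) &&
          mate_info$ifs >= metrics$concordant_lo &&
          mate_info$ifs <= metrics$concordant_hi
      } else TRUE
      if (!isTRUE(mate_info$same_chrom) ||
          !isTRUE(mate_info$proper_orientation) || !size_ok) {
        kinds <- c(kinds, "DISCORDANT_PAIR")
      }
    } else if (xor(isTRUE(read$mapped), mate_mapped)) {
      kinds <- c(kinds, "ONE_END_ANCHOR")
    }
  }
  kinds
}

empty_evidence <- function() {
  tibble(
    read_id = character(0), library_id = character(0),
    category = character(0), kind = character(0),
    chrom_a = character(0), pos_a = numeric(0), dir_a = character(0),
    mapq_a = numeric(0),
    chrom_b = character(0), pos_b = numeric(0), dir_b = character(0),
    mapq_b = numeric(0),
    l_sc = numeric(0), ifs = numeric(0),
    indel_op = character(0), indel_len = numeric(0),
    seq = character(0), qual = character(0), cigar = character(0),
    align_pos = numeric(0), strand = character(0), clip_side = character(0),
    ins_seq = character(0),
    mate_seq = character(0), mate_qual = character(0),
    mate_strand = character(0), mate_pos = numeric(0),
    mate_chrom = character(0), mate_cigar = character(0)
  )
}

ev_row <- function(...) {
  args <- list(...)
  row <- empty_evidence()[0, ]
  row[1, ] <- NA
  for (nm in names(args)) row[[nm]][1] <- args[[nm]]
  row
}

check_sorted <- function(mp) {
  if (nrow(mp) < 2) return(invisible())
  blocks <- rle(mp$chrom)$values
  if (anyDuplicated(blocks)) {
    abort("input not coordinate-sorted: chromosome blocks repeat")
  }
  bad <- which(diff(mp$pos) < 0 & mp$chrom[-1] == mp$chrom[-nrow(mp)])
  if (length(bad) > 0) {
    abort(sprintf("input not coordinate-sorted: record %d (%s at %s:%d)",
                  bad[1] + 1, mp$qname[bad[1] + 1], mp$chrom[bad[1] + 1],
                  mp$pos[bad[1] + 1]))
  }
  invisible()
}

#' Extract SV-supporting evidence from alignments
#'
#' @param x Coordinate-sorted SAM/BAM path or alignment tibble.
#' @param metrics Library metrics from [collect_metrics()].
#' @param category Sample category label for multi-sample calling.
#' @param min_clip Minimum soft-clip length retained (default 4 bp).
#' @param min_clip_baseq Minimum mean base quality of the clipped bases
#'   (default 5).
#' @param min_indel Minimum CIGAR I/D operation length emitting an INDEL
#'   record (default 1).
#' @return Evidence tibble ordered by (`chrom_a`, `pos_a`), one row per
#'   soft-clipped side / indel operation / discordant pair / one-end anchor.
#' @export
extract_evidence <- function(x, metrics, category = "default",
                             min_clip = 4, min_clip_baseq = 5,
                             min_indel = 1) {
  aln <- read_alignments(x)
  pr <- primary_records(aln) %>%
    mutate(mapq = if_else(.data$mapq == 255L,
                          as.integer(metrics$mapq_cap), .data$mapq))
  mp <- pr %>% filter(!flag_bit(.data$flag, 0x4))
  check_sorted(mp)
  lib <- metrics$library_id
  rows <- list()

  # ---- soft clips and indels -------------------------------------------
  if (nrow(mp) > 0) {
    clips <- cigar_clip(mp$cigar)
    refw <- cigar_ref_width(mp$cigar)
    for (side in c("5p", "3p")) {
      len <- if (side == "5p") clips$lead else clips$trail
      idx <- which(len >= min_clip)
      if (length(idx) == 0) next
      csq <- if (side == "5p") substr(mp$seq[idx], 1, len[idx]) else
        substr(mp$seq[idx], nchar(mp$seq[idx]) - len[idx] + 1,
               nchar(mp$seq[idx]))
      cq <- if (side == "5p") substr(mp$qual[idx], 1, len[idx]) else
        substr(mp$qual[idx], nchar(mp$qual[idx]) - len[idx] + 1,
               nchar(mp$qual[idx]))
      meanq <- vapply(qual_ints(cq), mean, numeric(1))
      ok <- meanq >= min_clip_baseq
      idx <- idx[ok]
      if (length(idx) == 0) next
      rows[[length(rows) + 1]] <- tibble(
        read_id = paste0(mp$qname[idx], "/",
                         if_else(flag_bit(mp$flag[idx], 0x40), "1", "2"),
                         "/", side),
        library_id = lib, category = category, kind = "SOFT_CLIP",
        chrom_a = mp$chrom[idx],
        pos_a = if (side == "3p") mp$pos[idx] + refw[idx] - 1 else mp$pos[idx],
        dir_a = if (side == "3p") "+" else "-",
        mapq_a = as.numeric(mp$mapq[idx]),
        l_sc = as.numeric(len[idx]),
        seq = mp$seq[idx], qual = mp$qual[idx], cigar = mp$cigar[idx],
        align_pos = as.numeric(mp$pos[idx]),
        strand = if_else(flag_bit(mp$flag[idx], 0x10), "-", "+"),
        clip_side = side
      )
    }
    has_indel <- which(stringr::str_detect(mp$cigar, "[0-9]+[ID]"))
    for (i in has_indel) {
      ops <- cigar_ops(mp$cigar[i])[[1]]
      refoff <- 0; qoff <- 0
      for (j in seq_along(ops$op)) {
        op <- ops$op[j]; ln <- ops$len[j]
        if (op %in% c("I", "D") && ln >= min_indel) {
          p <- mp$pos[i] + refoff - 1  # last aligned ref base before the op
          rows[[length(rows) + 1]] <- ev_row(
            read_id = paste0(mp$qname[i], "/",
                             if (flag_bit(mp$flag[i], 0x40)) "1" else "2",
                             "/", op, qoff),
            library_id = lib, category = category, kind = "INDEL",
            chrom_a = mp$chrom[i], pos_a = p, dir_a = "+",
            mapq_a = as.numeric(mp$mapq[i]),
            chrom_b = mp$chrom[i],
            pos_b = if (op == "D") p + ln + 1 else p + 1,
            dir_b = "-", mapq_b = as.numeric(mp$mapq[i]),
            indel_op = op, indel_len = as.numeric(ln),
            ins_seq = if (op == "I")
              substr(mp$seq[i], qoff + 1, qoff + ln) else NA_character_,
            seq = mp$seq[i], qual = mp$qual[i], cigar = mp$cigar[i],
            align_pos = as.numeric(mp$pos[i]),
            strand = if (flag_bit(mp$flag[i], 0x10)) "-" else "+"
          )
        }
        if (op %in% c("M", "D", "N", "=", "X")) refoff <- refoff + ln
        if (op %in% c("M", "I", "S", "=", "X")) qoff <- qoff + ln
      }
    }
  }

  # ---- read pairs -------------------------------------------------------
  pt <- pair_table(aln)
  if (nrow(pt) > 0) {
    pt <- pt %>%
      mutate(mapq_1 = if_else(.data$mapq_1 == 255L,
                              as.integer(metrics$mapq_cap), .data$mapq_1),
             mapq_2 = if_else(.data$mapq_2 == 255L,
                              as.integer(metrics$mapq_cap), .data$mapq_2))
    ifs <- pair_ifs(pt)
    proper <- pair_proper_orientation(pt)
    both <- pt$mapped_1 & pt$mapped_2
    size_bad <- if (metrics$pairs_available) {
      is.finite(ifs) & (ifs < metrics$concordant_lo |
                          ifs > metrics$concordant_hi)
    } else rep(FALSE, nrow(pt))
    is_dp <- both & (!proper | size_bad | !is.finite(ifs))
    is_oea <- xor(pt$mapped_1, pt$mapped_2)

    dp <- pt[is_dp, ]
    if (nrow(dp) > 0) {
      dp_ifs <- ifs[is_dp]
      # orient: read "a" is the genomically lower of the two
      a_first <- dp$chrom_1 < dp$chrom_2 |
        (dp$chrom_1 == dp$chrom_2 & dp$pos_1 <= dp$pos_2)
      pick <- function(f1, f2) ifelse(a_first, f1, f2)
      rows[[length(rows) + 1]] <- tibble(
        read_id = paste0(dp$qname, "/DP"),
        library_id = lib, category = category, kind = "DISCORDANT_PAIR",
        chrom_a = pick(dp$chrom_1, dp$chrom_2),
        pos_a = ifelse(pick(dp$strand_1, dp$strand_2) == "+",
                       pick(dp$ref_end_1, dp$ref_end_2),
                       pick(dp$pos_1, dp$pos_2)),
        dir_a = pick(dp$strand_1, dp$strand_2),
        mapq_a = as.numeric(pick(dp$mapq_1, dp$mapq_2)),
        chrom_b = pick(dp$chrom_2, dp$chrom_1),
        pos_b = ifelse(pick(dp$strand_2, dp$strand_1) == "+",
                       pick(dp$ref_end_2, dp$ref_end_1),
                       pick(dp$pos_2, dp$pos_1)),
        dir_b = pick(dp$strand_2, dp$strand_1),
        mapq_b = as.numeric(pick(dp$mapq_2, dp$mapq_1)),
        ifs = dp_ifs,
        seq = pick(dp$seq_1, dp$seq_2), qual = pick(dp$qual_1, dp$qual_2),
        cigar = pick(dp$cigar_1, dp$cigar_2),
        align_pos = as.numeric(pick(dp$pos_1, dp$pos_2)),
        strand = pick(dp$strand_1, dp$strand_2),
        mate_seq = pick(dp$seq_2, dp$seq_1),
        mate_qual = pick(dp$qual_2, dp$qual_1),
        mate_strand = pick(dp$strand_2, dp$strand_1),
        mate_pos = as.numeric(pick(dp$pos_2, dp$pos_1)),
        mate_chrom = pick(dp$chrom_2, dp$chrom_1),
        mate_cigar = pick(dp$cigar_2, dp$cigar_1)
      )
    }

    oea <- pt[is_oea, ]
    if (nrow(oea) > 0) {
      m1 <- oea$mapped_1
      pick <- function(f1, f2) ifelse(m1, f1, f2)
      rows[[length(rows) + 1]] <- tibble(
        read_id = paste0(oea$qname, "/OEA"),
        library_id = lib, category = category, kind = "ONE_END_ANCHOR",
        chrom_a = pick(oea$chrom_1, oea$chrom_2),
        pos_a = ifelse(pick(oea$strand_1, oea$strand_2) == "+",
                       pick(oea$ref_end_1, oea$ref_end_2),
                       pick(oea$pos_1, oea$pos_2)),
        dir_a = pick(oea$strand_1, oea$strand_2),
        mapq_a = as.numeric(pick(oea$mapq_1, oea$mapq_2)),
        seq = pick(oea$seq_1, oea$seq_2), qual = pick(oea$qual_1, oea$qual_2),
        cigar = pick(oea$cigar_1, oea$cigar_2),
        align_pos = as.numeric(pick(oea$pos_1, oea$pos_2)),
        strand = pick(oea$strand_1, oea$strand_2),
        mate_seq = pick(oea$seq_2, oea$seq_1),
        mate_qual = pick(oea$qual_2, oea$qual_1)
      )
    }
  }

  if (length(rows) == 0) return(empty_evidence())
  out <- bind_rows(empty_evidence(), bind_rows(rows))
  out %>% arrange(.data$chrom_a, .data$pos_a, .data$read_id)
}

#' Identify split reads by realigning soft-clipped bases
#'
#' Soft-clip records whose clipped bases realign uniquely to the reference
#' (mapping quality at least `min_mapq`) are upgraded to `SPLIT_READ` records
#' with the partner locus populated; others remain `SOFT_CLIP`.
#'
#' @param evidence Evidence tibble from [extract_evidence()].
#' @param reference Named character vector of reference sequences.
#' @param min_mapq Minimum realignment mapping quality (default 10).
#' @param min_len Minimum clip length submitted for realignment (default 18;
#'   shorter clips rarely map uniquely).
#' @param aligner Pluggable aligner: `function(query, anchor_chrom,
#'   anchor_pos)` returning a one-row tibble (`chrom`, `pos_start`,
#'   `pos_end`, `strand`, `mapq`, `q_start`, `q_end`) or `NULL`. Defaults to
#'   the internal Smith-Waterman window scan ([sw_genome_aligner()]).
#' @return The evidence tibble with qualifying rows upgraded.
#' @export
identify_split_reads <- function(evidence, reference, min_mapq = 10,
                                 min_len = 18, aligner = NULL) {
  if (is.null(aligner)) aligner <- sw_genome_aligner(reference)
  idx <- which(evidence$kind == "SOFT_CLIP" & evidence$l_sc >= min_len)
  for (i in idx) {
    r <- evidence[i, ]
    clip <- if (r$clip_side == "3p")
      substr(r$seq, nchar(r$seq) - r$l_sc + 1, nchar(r$seq))
    else substr(r$seq, 1, r$l_sc)
    hit <- tryCatch(aligner(clip, r$chrom_a, r$pos_a),
                    error = function(e) {
                      warn(sprintf("realignment failed for %s: %s",
                                   r$read_id, conditionMessage(e)))
                      NULL
                    })
    if (is.null(hit) || nrow(hit) == 0 || hit$mapq < min_mapq) next
    if ((hit$q_end - hit$q_start + 1) < 0.75 * r$l_sc) next
    # partner break-end: where does the clipped sequence continue?
    if (r$clip_side == "3p") {
      if (hit$strand == "+") { pos_b <- hit$pos_start; dir_b <- "-" }
      else { pos_b <- hit$pos_end; dir_b <- "+" }
    } else {
      if (hit$strand == "+") { pos_b <- hit$pos_end; dir_b <- "+" }
      else { pos_b <- hit$pos_start; dir_b <- "-" }
    }
    evidence$kind[i] <- "SPLIT_READ"
    evidence$chrom_b[i] <- hit$chrom
    evidence$pos_b[i] <- pos_b
    evidence$dir_b[i] <- dir_b
    evidence$mapq_b[i] <- hit$mapq
  }
  evidence
}
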