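# End-to-end pipeline: metrics -> extraction -> split-read identification ->
# scoring -> break-end assembly (forward and backward positional graphs per
# chromosome) -> contig realignment -> maximal-clique calling -> homology
# annotation -> VCF.

reverse_quals <- function(q) lapply(q, rev)

full_map_extent <- function(align_pos, cigar, seq) {
  cl <- cigar_clip(cigar)
  fs <- align_pos - cl$lead
  list(fs = fs, fe = fs + nchar(seq) - 1, lead = cl$lead, trail = cl$trail)
}

# query offset (bases consumed) just before the I/D op at reference offset
# `refoff` (1-based offset of the last aligned base before the op)
query_offset_at <- function(cigar, target_refoff) {
  ops <- cigar_ops(cigar)[[1]]
  refoff <- 0; qoff <- 0
  for (j in seq_along(ops$op)) {
    op <- ops$op[j]; ln <- ops$len[j]
    if (op %in% c("I", "D") && refoff == target_refoff) return(qoff)
    if (op %in% c("M", "D", "N", "=", "X")) refoff <- refoff + ln
    if (op %in% c("M", "I", "S", "=", "X")) qoff <- qoff + ln
  }
  NA_integer_
}

empty_greads <- function() {
  tibble(chrom = character(0), direction = character(0),
         read_id = character(0), seq = character(0), baseq = list(),
         mapq = numeric(0), start_lo = numeric(0), start_hi = numeric(0),
         anch_lo = numeric(0), anch_hi = numeric(0))
}

#' Convert evidence into positional-graph read placements
#'
#' Soft-clipped and split reads are placed at the single position implied by
#' full mapping of the read (anchored bases flagged); each read of a
#' discordant pair is placed, based on the anchoring location of its mate, at
#' every start position consistent with a concordant fragment; one-end-anchor
#' mates are placed across the full interval compatible with the mapped read.
#' Reads supporting a break after the anchor go to the forward graph of the
#' anchor chromosome; breaks before the anchor go to the backward graph,
#' realized by reflecting coordinates (and reverse-complementing sequence) so
#' a single forward assembly core serves both.
#'
#' @param evidence Evidence tibble (after [identify_split_reads()]).
#' @param metrics Library metrics.
#' @param ref_lengths Named integer vector of chromosome lengths.
#' @param min_indel_assembly Minimum indel-operation length treated as two
#'   independent soft-clipped reads for assembly (default 10 bp).
#' @return Graph-read tibble for [assemble_streaming()], one group per
#'   (`chrom`, `direction`).
#' @export
graph_reads_from_evidence <- function(evidence, metrics, ref_lengths,
                                      min_indel_assembly = 10) {
  rows <- list()
  refl <- function(chrom) ref_lengths[[chrom]] + 1
  add <- function(chrom, direction, read_id, seq, baseq, mapq, start_lo,
                  start_hi, anch_lo = NA_real_, anch_hi = NA_real_) {
    if (start_hi < 1) return()
    rows[[length(rows) + 1]] <<- tibble(
      chrom = chrom, direction = direction, read_id = read_id, seq = seq,
      baseq = list(baseq), mapq = mapq,
      start_lo = max(1, start_lo), start_hi = start_hi,
      anch_lo = anch_lo, anch_hi = anch_hi)
  }

  sc <- evidence %>% filter(.data$kind %in% c("SOFT_CLIP", "SPLIT_READ"))
  for (i in seq_len(nrow(sc))) {
    r <- sc[i, ]
    fm <- full_map_extent(r$align_pos, r$cigar, r$seq)
    n <- nchar(r$seq)
    bq <- qual_ints(r$qual)[[1]]
    if (r$clip_side == "3p") {
      add(r$chrom_a, "+", r$read_id, r$seq, bq, r$mapq_a, fm$fs, fm$fs,
          fm$lead + 1, n - fm$trail)
    } else {
      RF <- refl(r$chrom_a)
      add(r$chrom_a, "-", r$read_id, revcomp(r$seq), rev(bq), r$mapq_a,
          RF - fm$fe, RF - fm$fe, fm$trail + 1, n - fm$lead)
    }
  }

  ind <- evidence %>% filter(.data$kind == "INDEL",
                             .data$indel_len >= min_indel_assembly)
  for (i in seq_len(nrow(ind))) {
    r <- ind[i, ]
    fm <- full_map_extent(r$align_pos, r$cigar, r$seq)
    n <- nchar(r$seq)
    bq <- qual_ints(r$qual)[[1]]
    qoff <- query_offset_at(r$cigar, r$pos_a - r$align_pos + 1)
    if (is.na(qoff)) next
    # left side anchors, right side is effectively clipped (and vice versa)
    add(r$chrom_a, "+", paste0(r$read_id, "|L"), r$seq, bq, r$mapq_a,
        fm$fs, fm$fs, fm$lead + 1, qoff)
    RF <- refl(r$chrom_a)
    qafter <- if (r$indel_op == "I") qoff + r$indel_len else qoff
    add(r$chrom_a, "-", paste0(r$read_id, "|R"), revcomp(r$seq), rev(bq),
        r$mapq_a, RF - fm$fe, RF - fm$fe, fm$trail + 1, n - qafter)
  }

  if (metrics$pairs_available) {
    lo <- metrics$concordant_lo; hi <- metrics$concordant_hi
    place_mate <- function(anchor_chrom, anchor_strand, anchor_fs, anchor_fe,
                           anchor_mapq, placed_seq, placed_qual,
                           placed_strand, read_id) {
      n_m <- nchar(placed_seq)
      if (n_m == 0) return()
      bq <- qual_ints(placed_qual)[[1]]
      if (length(bq) == 0) bq <- rep(20L, n_m)
      if (anchor_strand == "+") {
        sfwd <- if (identical(placed_strand, "-")) placed_seq else
          revcomp(placed_seq)
        bqo <- if (identical(placed_strand, "-")) bq else rev(bq)
        add(anchor_chrom, "+", read_id, sfwd, bqo, anchor_mapq,
            anchor_fs + lo - n_m, anchor_fs + hi - n_m)
      } else {
        sfwd <- if (identical(placed_strand, "+")) placed_seq else
          revcomp(placed_seq)
        bqo <- if (identical(placed_strand, "+")) bq else rev(bq)
        RF <- refl(anchor_chrom)
        add(anchor_chrom, "-", read_id, revcomp(sfwd), rev(bqo), anchor_mapq,
            RF - anchor_fe + lo - n_m, RF - anchor_fe + hi - n_m)
      }
    }
    dp <- evidence %>% filter(.data$kind == "DISCORDANT_PAIR")
    for (i in seq_len(nrow(dp))) {
      r <- dp[i, ]
      fma <- full_map_extent(r$align_pos, r$cigar, r$seq)
      fmb <- full_map_extent(r$mate_pos, r$mate_cigar, r$mate_seq)
      place_mate(r$chrom_a, r$strand, fma$fs, fma$fe, r$mapq_a,
                 r$mate_seq, r$mate_qual, r$mate_strand,
                 paste0(r$read_id, "|B"))
      place_mate(r$chrom_b, r$mate_strand, fmb$fs, fmb$fe, r$mapq_b,
                 r$seq, r$qual, r$strand, paste0(r$read_id, "|A"))
    }
    oea <- evidence %>% filter(.data$kind == "ONE_END_ANCHOR")
    for (i in seq_len(nrow(oea))) {
      r <- oea[i, ]
      fma <- full_map_extent(r$align_pos, r$cigar, r$seq)
      place_mate(r$chrom_a, r$strand, fma$fs, fma$fe, r$mapq_a,
                 r$mate_seq, r$mate_qual, "+", paste0(r$read_id, "|M"))
    }
  }
  if (length(rows) == 0) return(empty_greads())
  bind_rows(rows)
}

strip_gread_suffix <- function(ids) sub("\\|[ABLRM]$", "", ids)

#' Assemble break-end contigs from extracted evidence
#'
#' Runs positional de Bruijn graph assembly per chromosome and break-end
#' direction and maps contigs back to reference coordinates.
#'
#' @param evidence Evidence tibble (after [identify_split_reads()]).
#' @param metrics Library metrics.
#' @param reference Named character vector of chromosome sequences.
#' @param k K-mer size (default 25).
#' @param min_support Minimum reads per contig (default 3).
#' @param streaming Streaming-window assembly (default) or whole-graph.
#' @return Contig tibble: `contig_id`, `chrom`, `direction`, `anchor_start`,
#'   `anchor_end`, `anchor_nodes`, `seq`/`anchored_seq`/`unanchored_seq`
#'   (reference-forward), `total_weight`, `n_support`, `support` (evidence
#'   read ids).
#' @export
assemble_evidence <- function(evidence, metrics, reference, k = 25,
                              min_support = 3, streaming = TRUE) {
  ref_lengths <- setNames(nchar(reference), names(reference))
  greads <- graph_reads_from_evidence(evidence, metrics, ref_lengths)
  read_len <- max(metrics$max_read_length, k + 1)
  out <- list()
  if (nrow(greads) > 0) {
    for (grp in dplyr::group_split(greads %>%
                                     group_by(.data$chrom, .data$direction))) {
      ch <- grp$chrom[1]; dirn <- grp$direction[1]
      grp <- grp %>% arrange(.data$start_lo)
      ctg <- assemble_streaming(
        grp %>% select(-"chrom", -"direction"), k = k,
        min_support = min_support, read_len = read_len,
        concordant_hi = if (metrics$pairs_available)
          metrics$concordant_hi else NULL,
        streaming = streaming)
      if (nrow(ctg) == 0) next
      RF <- ref_lengths[[ch]] + 1
      ctg <- ctg %>% mutate(chrom = ch, direction = dirn)
      if (dirn == "+") {
        ctg <- ctg %>% mutate(
          anchor_start = .data$start_pos,
          anchor_end = .data$start_pos +
            ifelse(.data$anchor_nodes > 0, .data$anchor_nodes + k - 2,
                   .data$n_nodes + k - 2))
      } else {
        ctg <- ctg %>% mutate(
          span_hi = .data$start_pos +
            ifelse(.data$anchor_nodes > 0, .data$anchor_nodes + k - 2,
                   .data$n_nodes + k - 2),
          anchor_start = RF - .data$span_hi,
          anchor_end = RF - .data$start_pos,
          seq = revcomp(.data$seq),
          anchored_seq = ifelse(nzchar(.data$anchored_seq),
                                revcomp(.data$anchored_seq), ""),
          unanchored_seq = revcomp(.data$unanchored_seq)
        ) %>% select(-"span_hi")
      }
      out[[length(out) + 1]] <- ctg
    }
  }
  if (length(out) == 0) {
    return(tibble(contig_id = character(0), chrom = character(0),
                  direction = character(0), anchor_start = numeric(0),
                  anchor_end = numeric(0), anchor_nodes = integer(0),
                  n_nodes = integer(0), seq = character(0),
                  anchored_seq = character(0), unanchored_seq = character(0),
                  total_weight = numeric(0), n_support = integer(0),
                  support = list()))
  }
  ctgs <- bind_rows(out) %>%
    mutate(support = lapply(.data$support, strip_gread_suffix),
           contig_id = sprintf("ctg_%04d", row_number())) %>%
    select("contig_id", "chrom", "direction", "anchor_start", "anchor_end",
           "anchor_nodes", "n_nodes", "seq", "anchored_seq",
           "unanchored_seq", "total_weight", "n_support", "support")
  ctgs
}

#' Convert scored read evidence into breakpoint-support tuples
#'
#' Split reads and indel reads give single-base breakpoint rectangles;
#' discordant pairs give the interval of breakpoint locations consistent
#' with a concordant placement of each anchor. Soft clips and one-end
#' anchors carry no partner locus and contribute only through assembly.
#'
#' @param evidence Scored evidence tibble (with `q`).
#' @param metrics Library metrics.
#' @return Breakpoint-evidence tibble with `w = q` and `origin` SR/DP.
#' @export
breakpoint_evidence_from_reads <- function(evidence, metrics) {
  rows <- list()
  sr <- evidence %>% filter(.data$kind %in% c("SPLIT_READ", "INDEL"),
                            !is.na(.data$chrom_b))
  for (i in seq_len(nrow(sr))) {
    r <- sr[i, ]
    left <- list(chrom = r$chrom_a, pos = r$pos_a, dir = r$dir_a)
    right <- list(chrom = r$chrom_b, pos = r$pos_b, dir = r$dir_b)
    unt <- if (!is.na(r$ins_seq)) r$ins_seq else ""
    rows[[length(rows) + 1]] <- canonical_bp_row(
      r$read_id, left, right, unt, "SR", r$mapq_b, TRUE) %>%
      mutate(w = r$q, read_id = r$read_id, category = r$category)
  }
  dp <- evidence %>% filter(.data$kind == "DISCORDANT_PAIR")
  if (metrics$pairs_available && nrow(dp) > 0) {
    hi <- metrics$concordant_hi
    for (i in seq_len(nrow(dp))) {
      r <- dp[i, ]
      fma <- full_map_extent(r$align_pos, r$cigar, r$seq)
      fmb <- full_map_extent(r$mate_pos, r$mate_cigar, r$mate_seq)
      int_a <- if (r$dir_a == "+") c(r$pos_a, fma$fs + hi - 1) else
        c(fma$fe - hi + 1, r$pos_a)
      int_b <- if (r$dir_b == "+") c(r$pos_b, fmb$fs + hi - 1) else
        c(fmb$fe - hi + 1, r$pos_b)
      flip <- (r$chrom_b < r$chrom_a) ||
        (r$chrom_b == r$chrom_a && int_b[1] < int_a[1])
      if (flip) { tmp <- int_a; int_a <- int_b; int_b <- tmp }
      rows[[length(rows) + 1]] <- tibble(
        contig_id = NA_character_,
        chrom_l = if (flip) r$chrom_b else r$chrom_a,
        s_l = int_a[1], e_l = int_a[2],
        dir_l = if (flip) r$dir_b else r$dir_a,
        chrom_h = if (flip) r$chrom_a else r$chrom_b,
        s_h = int_b[1], e_h = int_b[2],
        dir_h = if (flip) r$dir_a else r$dir_b,
        untemplated = "", origin = "DP", realign_mapq = r$mapq_b,
        anchor_side = NA_character_, w = r$q, read_id = r$read_id,
        category = r$category)
    }
  }
  if (length(rows) == 0) {
    return(empty_breakpoints() %>%
             mutate(w = numeric(0), read_id = character(0),
                    category = character(0)))
  }
  bind_rows(rows)
}

#' Call structural variants end to end
#'
#' Runs the full pipeline on one or more coordinate-sorted alignment inputs
#' sharing a reference: library metrics, evidence extraction, split-read
#' identification, scoring, break-end assembly, contig realignment,
#' maximal-clique variant calling, homology annotation and confidence
#' classification.
#'
#' @param x Alignment input (SAM/BAM path or tibble) or a list of them for
#'   multi-sample calling.
#' @param reference Named character vector of chromosome sequences (or a
#'   FASTA path).
#' @param categories Per-input category labels (defaults to input names).
#' @param k K-mer size for assembly (default 25).
#' @param min_support Minimum reads per assembly (default 3).
#' @param qual_threshold High-confidence quality threshold (default 500).
#' @param max_ihom_window Inexact homology window (default 300).
#' @param output_vcf Optional VCF output path.
#' @param streaming Streaming-window assembly (default TRUE).
#' @return An `sv_result` list: `calls`, `single_breakends`, `contigs`,
#'   `evidence`, `breakpoint_evidence`, `metrics`.
#' @export
sv_call <- function(x, reference, categories = NULL, k = 25,
                    min_support = 3, qual_threshold = 500,
                    max_ihom_window = 300, output_vcf = NULL,
                    streaming = TRUE) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_genome_fasta(reference)
  }
  inputs <- if (is.data.frame(x) || is.character(x)) list(x) else x
  if (is.null(categories)) {
    categories <- if (!is.null(names(inputs))) names(inputs)
    else paste0("sample", seq_along(inputs))
  }
  aligner <- sw_genome_aligner(reference)
  metrics_list <- list()
  ev_list <- list()
  for (i in seq_along(inputs)) {
    m <- collect_metrics(inputs[[i]])
    m$library_id <- paste0(m$library_id, "#", i)
    metrics_list[[m$library_id]] <- m
    e <- extract_evidence(inputs[[i]], m, category = categories[[i]])
    e$library_id <- m$library_id
    e <- identify_split_reads(e, reference, aligner = aligner)
    ev_list[[i]] <- score_evidence(e, m)
  }
  evidence <- bind_rows(ev_list) %>%
    arrange(.data$chrom_a, .data$pos_a, .data$read_id)
  # pooled assembly across categories; per-library metrics drive placement,
  # approximated here by the first library's bounds (single-library default)
  metrics <- metrics_list[[1]]
  contigs <- assemble_evidence(evidence, metrics, reference, k = k,
                               min_support = min_support,
                               streaming = streaming)
  # realign contigs and score assemblies
  asm_rows <- list()
  for (i in seq_len(nrow(contigs))) {
    ctg <- contigs[i, ]
    bp <- realign_contig(ctg, reference, metrics, aligner = aligner)
    if (nrow(bp) == 0) next
    cons <- evidence %>% filter(.data$read_id %in% ctg$support[[1]])
    if (nrow(cons) == 0) next
    bp$w <- vapply(bp$realign_mapq, function(mq) {
      score_assembly(cons, mq, metrics)
    }, numeric(1))
    bp$read_id <- paste0(ctg$contig_id, "#", seq_len(nrow(bp)))
    bp$category <- cons$category[1]
    asm_rows[[length(asm_rows) + 1]] <- bp
  }
  read_bps <- breakpoint_evidence_from_reads(evidence, metrics)
  all_bps <- bind_rows(read_bps, bind_rows(asm_rows))
  single <- all_bps %>% filter(is.na(.data$chrom_h))
  paired <- all_bps %>% filter(!is.na(.data$chrom_h))
  paired <- expand_exact_rows(paired, reference)
  cliques <- enumerate_maximal_cliques(paired)
  calls <- greedy_assign(cliques, paired)
  calls <- summarise_support(calls, paired)
  calls <- annotate_homology(calls, reference,
                             max_ihom_window = max_ihom_window)
  calls <- classify_confidence(calls, qual_threshold = qual_threshold)
  sb <- if (nrow(single) > 0) {
    single %>%
      mutate(pos_l = .data$s_l, qual = .data$w) %>%
      select("chrom_l", "pos_l", "dir_l", "qual", "untemplated")
  } else NULL
  if (!is.null(output_vcf)) {
    write_vcf(calls, reference, output_vcf, single_breakends = sb)
  }
  structure(list(calls = calls, single_breakends = sb, contigs = contigs,
                 evidence = evidence, breakpoint_evidence = paired,
                 metrics = metrics_list, reference_names = names(reference)),
            class = "sv_result")
}

# per-call support breakdown, assembly sides and untemplated sequence
summarise_support <- function(calls, bps) {
  n <- nrow(calls)
  add <- tibble(n_sr = integer(n), n_dp = integer(n), n_as = integer(n),
                q_sr = numeric(n), q_dp = numeric(n), q_as = numeric(n),
                assembly_sides = integer(n), support_cat = character(n),
                untemplated = character(n),
                junc_l = NA_real_, junc_h = NA_real_)
  for (i in seq_len(n)) {
    m <- bps[calls$members[[i]], ]
    add$n_sr[i] <- sum(m$origin == "SR")
    add$n_dp[i] <- sum(m$origin == "DP")
    add$n_as[i] <- sum(m$origin == "ASSEMBLY")
    add$q_sr[i] <- sum(m$w[m$origin == "SR"])
    add$q_dp[i] <- sum(m$w[m$origin == "DP"])
    add$q_as[i] <- sum(m$w[m$origin == "ASSEMBLY"])
    add$assembly_sides[i] <-
      dplyr::n_distinct(m$anchor_side[m$origin == "ASSEMBLY" &
                                        !is.na(m$anchor_side)])
    cats <- m %>% group_by(.data$category) %>%
      summarise(n = dplyr::n(), q = sum(.data$w), .groups = "drop")
    add$support_cat[i] <- paste(sprintf("%s:%d:%.0f", cats$category,
                                        cats$n, cats$q), collapse = ",")
    exact <- m %>% filter(!is.na(.data$j_l)) %>%
      arrange(desc(.data$origin == "ASSEMBLY"), desc(.data$w))
    if (nrow(exact) > 0) {
      add$untemplated[i] <- if (!is.na(exact$untemplated[1]))
        exact$untemplated[1] else ""
      add$junc_l[i] <- exact$j_l[1]
      add$junc_h[i] <- exact$j_h[1]
    }
  }
  bind_cols(calls, add)
}

#' @export
print.sv_result <- function(x, ...) {
  cat("<sv_result>\n")
  cat(sprintf("  %d breakpoint call(s), %d high-confidence\n",
              nrow(x$calls), sum(x$calls$confidence == "HIGH")))
  cat(sprintf("  %d contig(s), %d evidence record(s)\n",
              nrow(x$contigs), nrow(x$evidence)))
  invisible(x)
}
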