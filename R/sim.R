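# Synthetic-data generation: random reference genomes, planted structural
# variants with an exact truth record, and simulated paired-end reads with
# truth alignments projected onto the reference (junction-crossing reads are
# emitted soft-clipped, junction-spanning pairs become discordant), so every
# pipeline stage is testable without an external aligner or downloads.

#' Generate a random reference genome
#'
#' @param lengths Integer vector of chromosome lengths (bp, each >= 1000).
#' @param gc GC fraction (0 gives an A/T-only sequence).
#' @param seed RNG seed; the sequence is deterministic given the seed.
#' @param chrom_names Chromosome names (default `chr1`, `chr2`, ...).
#' @param lowcomplex Optional tibble(`chrom`, `start`, `len`, `unit`) of
#'   low-complexity tracts to overwrite (e.g. unit `"AT"`), for
#'   error-correction stress tests.
#' @return Named character vector of chromosome sequences.
#' @export
sim_genome <- function(lengths, gc = 0.5, seed = 1, chrom_names = NULL,
                       lowcomplex = NULL) {
  stopifnot(all(lengths >= 1000))
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_along(lengths))
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    genome <- vapply(lengths, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  names(genome) <- chrom_names
  if (!is.null(lowcomplex)) {
    for (i in seq_len(nrow(lowcomplex))) {
      tr <- lowcomplex[i, ]
      tract <- strtrim(strrep(tr$unit, ceiling(tr$len / nchar(tr$unit))), tr$len)
      substr(genome[tr$chrom], tr$start, tr$start + tr$len - 1) <- tract
    }
  }
  genome
}

#' Write / read a genome as FASTA
#' @param genome Named character vector of sequences.
#' @param path FASTA file path.
#' @return `path` (write) or a named character vector (read).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Plant structural variants into a genome
#'
#' Supported event types: `DEL`, `INS` (untemplated insertion of `seq`),
#' `INV`, `DUP` (tandem), `TRA` (reciprocal translocation; uses `chrom2`,
#' `pos2`, and the two chromosomes must carry no other event). `DEL` events
#' may request `hom_len` bases of junction microhomology, which is planted by
#' copying the flank into the returned reference before deleting (boundary
#' bases are forced to mismatch so the realized homology is exact).
#'
#' @param genome Named character vector from [sim_genome()].
#' @param events Tibble with columns `type`, `chrom`, `pos`, `size` and
#'   optionally `hom_len`, `seq`, `chrom2`, `pos2`, `zygosity`
#'   (`"het"`/`"hom"`, default het).
#' @param seed RNG seed (used for homology boundary substitutions).
#' @return List: `reference` (possibly homology-adjusted), `mutated` (the
#'   variant haplotype), `segments` (the mutated-to-reference segment map),
#'   `truth` (one row per junction: `chrom_l`, `pos_l`, `dir_l`, `chrom_h`,
#'   `pos_h`, `dir_h`, `hom_len`, `untemplated`, `type`, `zygosity`).
#' @export
sim_plant_svs <- function(genome, events, seed = 1) {
  events <- as_tibble(events)
  if (!"hom_len" %in% names(events)) events$hom_len <- 0L
  if (!"seq" %in% names(events)) events$seq <- NA_character_
  if (!"zygosity" %in% names(events)) events$zygosity <- "het"
  if (!"chrom2" %in% names(events)) events$chrom2 <- NA_character_
  if (!"pos2" %in% names(events)) events$pos2 <- NA_integer_
  events$hom_len[is.na(events$hom_len)] <- 0L

  # overlap check (per chromosome, 1 bp of breathing room)
  iv <- events %>%
    filter(.data$type != "TRA") %>%
    mutate(start = .data$pos, end = .data$pos + pmax(.data$size, 1))
  ov <- iv %>% arrange(.data$chrom, .data$start) %>% group_by(.data$chrom) %>%
    filter(.data$start <= lag(.data$end, default = -Inf)) %>% ungroup()
  if (nrow(ov) > 0) abort("planted events overlap")
  tra <- events %>% filter(.data$type == "TRA")
  if (nrow(tra) > 0) {
    busy <- unique(c(tra$chrom, tra$chrom2))
    if (any(iv$chrom %in% busy))
      abort("TRA chromosomes must carry no other event")
  }

  # plant requested DEL microhomology into the reference
  withr::with_seed(seed, {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$type != "DEL" || e$hom_len == 0) next
      m <- e$hom_len
      hom <- substr(genome[e$chrom], e$pos + 1, e$pos + m)
      substr(genome[e$chrom], e$pos + e$size + 1, e$pos + e$size + m) <- hom
      # force mismatches just outside the planted homology
      fix <- function(keep_pos, edit_pos) {
        a <- substr(genome[e$chrom], keep_pos, keep_pos)
        b <- substr(genome[e$chrom], edit_pos, edit_pos)
        if (a == b) {
          substr(genome[[e$chrom]], edit_pos, edit_pos) <<-
            sample(setdiff(c("A", "C", "G", "T"), a), 1)
        }
      }
      fix(e$pos + m + 1, e$pos + e$size + m + 1)
      fix(e$pos, e$pos + e$size)
    }
  })

  # build segment lists per mutated chromosome
  seg <- function(chrom, start, end, strand = "+", ins = NA_character_) {
    tibble(ref_chrom = chrom, ref_start = start, ref_end = end,
           strand = strand, ins_seq = ins)
  }
  seg_lists <- lapply(names(genome), function(ch) {
    ev <- events %>% filter(.data$type != "TRA", .data$chrom == ch) %>%
      arrange(.data$pos)
    L <- unname(nchar(genome[ch]))
    segs <- list()
    cur <- 1
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$pos >= cur) segs <- c(segs, list(seg(ch, cur, e$pos)))
      if (e$type == "DEL") {
        cur <- e$pos + e$size + 1
      } else if (e$type == "INS") {
        segs <- c(segs, list(seg(NA, NA, NA, ins = e$seq)))
        cur <- e$pos + 1
      } else if (e$type == "INV") {
        segs <- c(segs, list(seg(ch, e$pos + 1, e$pos + e$size, "-")))
        cur <- e$pos + e$size + 1
      } else if (e$type == "DUP") {
        segs <- c(segs, list(seg(ch, e$pos + 1, e$pos + e$size),
                             seg(ch, e$pos + 1, e$pos + e$size)))
        cur <- e$pos + e$size + 1
      }
    }
    if (cur <= L) segs <- c(segs, list(seg(ch, cur, L)))
    bind_rows(segs)
  })
  names(seg_lists) <- names(genome)
  for (i in seq_len(nrow(tra))) {
    e <- tra[i, ]
    la <- unname(nchar(genome[e$chrom])); lb <- unname(nchar(genome[e$chrom2]))
    seg_lists[[e$chrom]] <- bind_rows(seg(e$chrom, 1, e$pos),
                                      seg(e$chrom2, e$pos2, lb))
    seg_lists[[e$chrom2]] <- bind_rows(seg(e$chrom2, 1, e$pos2 - 1),
                                       seg(e$chrom, e$pos + 1, la))
  }

  # merge reference-adjacent neighbouring segments (e.g. the second copy of a
  # tandem duplication running onto the downstream sequence) so reads crossing
  # a reference-contiguous boundary are not artificially split
  merge_adjacent <- function(s) {
    keep <- list()
    for (i in seq_len(nrow(s))) {
      if (length(keep) > 0) {
        last <- keep[[length(keep)]]
        joinable <- !is.na(last$ref_chrom) && !is.na(s$ref_chrom[i]) &&
          last$ref_chrom == s$ref_chrom[i] && last$strand == s$strand[i] &&
          ((last$strand == "+" && s$ref_start[i] == last$ref_end + 1) ||
             (last$strand == "-" && s$ref_end[i] == last$ref_start - 1))
        if (joinable) {
          if (last$strand == "+") last$ref_end <- s$ref_end[i]
          else last$ref_start <- s$ref_start[i]
          keep[[length(keep)]] <- last
          next
        }
      }
      keep[[length(keep) + 1]] <- s[i, ]
    }
    bind_rows(keep)
  }
  seg_lists <- lapply(seg_lists, merge_adjacent)

  segments <- purrr::imap(seg_lists, function(s, ch) {
    s$mut_chrom <- ch
    s$len <- ifelse(is.na(s$ref_chrom), nchar(s$ins_seq),
                    s$ref_end - s$ref_start + 1)
    s$mut_end <- cumsum(s$len)
    s$mut_start <- s$mut_end - s$len + 1
    s
  }) %>% bind_rows()

  mutated <- vapply(names(genome), function(ch) {
    s <- segments %>% filter(.data$mut_chrom == ch)
    paste(purrr::pmap_chr(s, function(ref_chrom, ref_start, ref_end, strand,
                                      ins_seq, ...) {
      if (is.na(ref_chrom)) return(ins_seq)
      x <- substr(genome[ref_chrom], ref_start, ref_end)
      if (strand == "-") revcomp(x) else x
    }), collapse = "")
  }, character(1))

  truth <- truth_from_segments(genome, segments, events)
  list(reference = genome, mutated = mutated, segments = segments,
       truth = truth)
}

# break-end of a segment boundary: left = trailing end of s1, right = leading
# end of s2
segment_breakends <- function(s1, s2) {
  left <- if (s1$strand == "+") {
    list(chrom = s1$ref_chrom, pos = s1$ref_end, dir = "+")
  } else {
    list(chrom = s1$ref_chrom, pos = s1$ref_start, dir = "-")
  }
  right <- if (s2$strand == "+") {
    list(chrom = s2$ref_chrom, pos = s2$ref_start, dir = "-")
  } else {
    list(chrom = s2$ref_chrom, pos = s2$ref_end, dir = "+")
  }
  list(left = left, right = right)
}

truth_from_segments <- function(reference, segments, events) {
  rows <- list()
  for (ch in unique(segments$mut_chrom)) {
    s <- segments %>% filter(.data$mut_chrom == ch) %>%
      arrange(.data$mut_start)
    i <- 1
    while (i < nrow(s)) {
      s1 <- s[i, ]; j <- i + 1
      unt <- ""
      if (is.na(s$ref_chrom[j])) { unt <- s$ins_seq[j]; j <- j + 1 }
      if (j > nrow(s)) break
      s2 <- s[j, ]
      # reference-adjacent boundary (no junction)
      adjacent <- !is.na(s1$ref_chrom) && !is.na(s2$ref_chrom) &&
        unt == "" && s1$ref_chrom == s2$ref_chrom &&
        s1$strand == "+" && s2$strand == "+" &&
        s2$ref_start == s1$ref_end + 1
      if (!adjacent) {
        be <- segment_breakends(s1, s2)
        rows[[length(rows) + 1]] <- canonical_junction_row(
          reference, be$left, be$right, unt)
      }
      i <- j
    }
  }
  tr <- bind_rows(rows) %>% distinct()
  # zygosity/type are event-level descriptors; attach the nearest event
  tr$type <- NA_character_; tr$zygosity <- "het"
  for (i in seq_len(nrow(tr))) {
    d <- abs(events$pos - tr$pos_l[i])
    d[events$chrom != tr$chrom_l[i] & !(events$type == "TRA")] <- Inf
    if (any(is.finite(d))) {
      j <- which.min(d)
      tr$type[i] <- events$type[j]
      tr$zygosity[i] <- events$zygosity[j]
    }
  }
  tr
}

canonical_junction_row <- function(reference, left, right, untemplated) {
  # order the two break-ends by genome coordinate
  flip <- (right$chrom < left$chrom) ||
    (right$chrom == left$chrom && right$pos < left$pos)
  if (flip) {
    tmp <- left; left <- right; right <- tmp
    if (untemplated != "") untemplated <- revcomp(untemplated)
  }
  hom <- junction_homology(reference, left$chrom, left$pos, left$dir,
                           right$chrom, right$pos, right$dir, untemplated)
  tibble(chrom_l = left$chrom, pos_l = left$pos, dir_l = left$dir,
         chrom_h = right$chrom, pos_h = right$pos, dir_h = right$dir,
         hom_len = hom$homlen, hom_lo = hom$lo, hom_hi = hom$hi,
         untemplated = untemplated)
}

#' Simulate paired-end reads with truth alignments
#'
#' Fragments are drawn uniformly from the given haplotypes with
#' normal(frag_mean, frag_sd) sizes; each end yields a read with
#' substitution errors at `error_rate` and base qualities at the Phred
#' equivalent of the error rate with +/-5 jitter. Alignments are projected
#' onto the reference through the segment map: junction-crossing reads are
#' soft-clipped at the junction, reads falling entirely inside untemplated
#' insertions are unmapped.
#'
#' @param haplotypes List of genomes (named character vectors) sampled with
#'   `weights`; pass `list(reference, mutated)` with equal weights for a
#'   heterozygous sample.
#' @param segment_maps List parallel to `haplotypes`: `NULL` for the
#'   reference itself, or the `segments` tibble from [sim_plant_svs()].
#' @param coverage Total haploid-equivalent coverage (x).
#' @param read_len,frag_mean,frag_sd Read length and fragment-size model (bp).
#' @param error_rate Per-base substitution rate.
#' @param seed RNG seed (byte-identical output for a fixed seed).
#' @param weights Haplotype sampling weights (default equal).
#' @param library_id Library name recorded with the reads.
#' @return Alignment tibble (`qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `mchrom`, `mpos`, `seq`, `qual`, ...) sorted by coordinate;
#'   write it with [write_sam()].
#' @export
sim_reads <- function(haplotypes, segment_maps, coverage, read_len = 100,
                      frag_mean = 300, frag_sd = 30, error_rate = 0.01,
                      seed = 1, weights = NULL, library_id = "lib1") {
  if (coverage <= 0) abort("coverage must be positive")
  if (frag_mean < read_len) abort("frag_mean must be >= read_len")
  if (is.null(weights)) weights <- rep(1, length(haplotypes))
  weights <- weights / sum(weights)
  recs <- withr::with_seed(seed, {
    out <- list()
    for (h in seq_along(haplotypes)) {
      hap <- haplotypes[[h]]
      segs <- segment_maps[[h]]
      for (ch in names(hap)) {
        L <- nchar(hap[ch])
        nf <- round(coverage * weights[h] * L / (2 * read_len))
        if (nf == 0) next
        fs <- pmax(read_len + 2, round(rnorm(nf, frag_mean, frag_sd)))
        st <- floor(runif(nf, 1, pmax(2, L - fs)))
        out[[length(out) + 1]] <- sim_fragments(
          hap, segs, ch, st, fs, read_len, error_rate,
          prefix = sprintf("frag_h%d_%s", h, ch))
      }
    }
    bind_rows(out)
  })
  recs$mapq <- ifelse(bitwAnd(recs$flag, 4L) > 0, 0L, 60L)
  recs$library_id <- library_id
  # fill mate fields and coordinate-sort (unmapped reads sit at their mate)
  recs <- recs[order(recs$qname), ]   # exactly two records per fragment
  idx <- seq_len(nrow(recs))
  mate <- ifelse(idx %% 2 == 1, idx + 1, idx - 1)
  recs <- recs %>%
    mutate(
      mchrom = .data$chrom[mate], mpos = .data$pos[mate],
      mflag = .data$flag[mate]
    ) %>%
    mutate(
      chrom = if_else(bitwAnd(.data$flag, 4L) > 0, .data$mchrom, .data$chrom),
      pos = if_else(bitwAnd(.data$flag, 4L) > 0, .data$mpos, .data$pos),
      flag = .data$flag +
        if_else(bitwAnd(.data$mflag, 4L) > 0, 8L, 0L) +
        if_else(bitwAnd(.data$mflag, 16L) > 0, 32L, 0L)
    ) %>%
    select(-"mflag") %>%
    arrange(is.na(.data$chrom), .data$chrom, .data$pos)
  recs
}

# simulate both reads of each fragment on one haplotype chromosome and
# project them onto the reference
sim_fragments <- function(hap, segs, ch, starts, sizes, read_len,
                          error_rate, prefix) {
  n <- length(starts)
  ends <- starts + sizes - 1
  r1s <- starts; r1e <- starts + read_len - 1
  r2s <- ends - read_len + 1; r2e <- ends
  raw1 <- substring(hap[ch], r1s, r1e)
  raw2 <- revcomp(substring(hap[ch], r2s, r2e))
  add_errors <- function(sq) {
    nerr <- rbinom(length(sq), read_len, error_rate)
    idx <- which(nerr > 0)
    for (i in idx) {
      p <- sample.int(read_len, nerr[i])
      for (pp in p) {
        old <- substr(sq[i], pp, pp)
        substr(sq[i], pp, pp) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
    sq
  }
  raw1 <- add_errors(raw1); raw2 <- add_errors(raw2)
  q0 <- round(-10 * log10(max(error_rate, 1e-4)))
  jit <- function() pmax(2L, q0 + sample(-5:5, read_len, replace = TRUE))
  qual1 <- vapply(seq_len(n), function(i) qual_string(jit()), character(1))
  qual2 <- vapply(seq_len(n), function(i) qual_string(jit()), character(1))
  qname <- sprintf("%s_%06d", prefix, seq_len(n))
  a1 <- project_reads(segs, ch, r1s, r1e, raw1, qual1, raw_strand = "+")
  a2 <- project_reads(segs, ch, r2s, r2e, raw2, qual2, raw_strand = "-")
  a1$qname <- qname; a2$qname <- qname
  a1$flag <- a1$flag + 1L + 64L
  a2$flag <- a2$flag + 1L + 128L
  bind_rows(a1, a2)
}

# Project reads on a (possibly mutated) chromosome onto the reference.
# starts/ends are haplotype coordinates; raw is the as-sequenced read
# (raw_strand gives its orientation relative to the haplotype).
project_reads <- function(segs, ch, starts, ends, raw, qual, raw_strand) {
  n <- length(starts)
  if (is.null(segs)) {
    # haplotype IS the reference
    seq <- if (raw_strand == "+") raw else revcomp(raw)
    qual_out <- if (raw_strand == "+") qual else
      vapply(strsplit(qual, ""), function(x) paste(rev(x), collapse = ""),
             character(1))
    return(tibble(
      chrom = ch, pos = starts, flag = if (raw_strand == "-") 16L else 0L,
      cigar = paste0(ends - starts + 1, "M"), seq = seq, qual = qual_out))
  }
  s <- segs %>% filter(.data$mut_chrom == ch) %>% arrange(.data$mut_start)
  iv_start <- s$mut_start
  seg_of <- function(p) findInterval(p, iv_start)
  i1 <- seg_of(starts); i2 <- seg_of(ends)
  # fast path: reads contained in a single reference segment
  fast <- i1 == i2 & !is.na(s$ref_chrom[i1])
  fast_tbl <- NULL
  if (any(fast)) {
    fi <- i1[fast]
    str_f <- s$strand[fi]
    plus <- str_f == "+"
    ref_lo <- ifelse(plus, s$ref_start[fi] + (starts[fast] - s$mut_start[fi]),
                     s$ref_end[fi] - (ends[fast] - s$mut_start[fi]))
    mlen <- ends[fast] - starts[fast] + 1
    mutfwd <- ifelse(rep(raw_strand == "+", sum(fast)), raw[fast],
                     revcomp(raw[fast]))
    qmut <- if (raw_strand == "+") qual[fast] else
      vapply(strsplit(qual[fast], ""), function(x)
        paste(rev(x), collapse = ""), character(1))
    seq_out <- ifelse(plus, mutfwd, revcomp(mutfwd))
    qual_out <- ifelse(plus, qmut,
                       vapply(strsplit(qmut, ""), function(x)
                         paste(rev(x), collapse = ""), character(1)))
    strand_flag <- ifelse(plus == (raw_strand == "+"), 0L, 16L)
    fast_tbl <- tibble(.idx = which(fast), chrom = s$ref_chrom[fi],
                       pos = as.integer(ref_lo), flag = strand_flag,
                       cigar = paste0(mlen, "M"), seq = seq_out,
                       qual = qual_out)
  }
  out <- vector("list", n)
  for (i in which(!fast)) {
    pieces <- s[i1[i]:i2[i], ]
    # primary segment: the reference segment with the longest overlap
    ovl <- pmin(pieces$mut_end, ends[i]) - pmax(pieces$mut_start, starts[i]) + 1
    ovl[is.na(pieces$ref_chrom)] <- -1
    if (all(ovl < 0)) {
      out[[i]] <- tibble(chrom = NA_character_, pos = NA_integer_, flag = 4L,
                         cigar = "*", seq = raw[i], qual = qual[i])
      next
    }
    p <- pieces[which.max(ovl), ]
    os <- max(p$mut_start, starts[i]); oe <- min(p$mut_end, ends[i])
    # reference coordinates of the aligned run
    if (p$strand == "+") {
      ref_lo <- p$ref_start + (os - p$mut_start)
      ref_hi <- p$ref_start + (oe - p$mut_start)
    } else {
      ref_lo <- p$ref_end - (oe - p$mut_start)
      ref_hi <- p$ref_end - (os - p$mut_start)
    }
    L <- ends[i] - starts[i] + 1
    lead_mut <- os - starts[i]       # clipped bases before run, mut-forward
    trail_mut <- ends[i] - oe
    mlen <- oe - os + 1
    # SEQ orientation is reference-forward: mut-forward if segment '+',
    # reverse-complement otherwise
    mutfwd <- if (raw_strand == "+") raw[i] else revcomp(raw[i])
    qmut <- if (raw_strand == "+") qual[i] else paste(rev(strsplit(qual[i], "")[[1]]), collapse = "")
    if (p$strand == "+") {
      seq_out <- mutfwd; qual_out <- qmut
      cig <- paste0(ifelse(lead_mut > 0, paste0(lead_mut, "S"), ""),
                    mlen, "M",
                    ifelse(trail_mut > 0, paste0(trail_mut, "S"), ""))
      strand_flag <- if (raw_strand == "+") 0L else 16L
    } else {
      seq_out <- revcomp(mutfwd)
      qual_out <- paste(rev(strsplit(qmut, "")[[1]]), collapse = "")
      cig <- paste0(ifelse(trail_mut > 0, paste0(trail_mut, "S"), ""),
                    mlen, "M",
                    ifelse(lead_mut > 0, paste0(lead_mut, "S"), ""))
      strand_flag <- if (raw_strand == "+") 16L else 0L
    }
    out[[i]] <- tibble(chrom = p$ref_chrom, pos = as.integer(ref_lo),
                       flag = strand_flag, cigar = cig,
                       seq = seq_out, qual = qual_out)
  }
  slow_tbl <- bind_rows(out)
  if (nrow(slow_tbl) > 0) slow_tbl$.idx <- which(!fast)
  bind_rows(fast_tbl, slow_tbl) %>%
    arrange(.data$.idx) %>%
    select(-".idx")
}

#' Write an alignment tibble as a coordinate-sorted SAM file
#'
#' @param aln Alignment tibble from [sim_reads()].
#' @param ref_lengths Named integer vector of reference chromosome lengths
#'   (or a genome from [sim_genome()], whose `nchar` is used).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  if (is.character(ref_lengths) && !is.null(names(ref_lengths)) &&
      !is.numeric(ref_lengths)) {
    ref_lengths <- setNames(nchar(ref_lengths), names(ref_lengths))
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  aln <- aln %>% arrange(is.na(.data$chrom), .data$chrom, .data$pos)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                  aln$qname, aln$flag,
                  ifelse(is.na(aln$chrom), "*", aln$chrom),
                  ifelse(is.na(aln$pos), 0L, aln$pos),
                  aln$mapq, aln$cigar,
                  ifelse(is.na(aln$mchrom), "*",
                         ifelse(aln$mchrom == aln$chrom & !is.na(aln$chrom),
                                "=", aln$mchrom)),
                  ifelse(is.na(aln$mpos), 0L, aln$mpos),
                  aln$seq, aln$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' One-call synthetic SV dataset
#'
#' A 100 kb two-chromosome genome with a planted heterozygous 500 bp
#' deletion, 1 kb tandem duplication, 2 kb inversion and a reciprocal
#' translocation, sequenced at the given coverage with 2x100 bp reads
#' (fragment 300 +/- 30, 1% error).
#'
#' @param seed RNG seed controlling genome, events and reads.
#' @param coverage Sequencing depth (default 60).
#' @return List: `reference`, `truth`, `aln` (alignment tibble), `events`.
#' @export
sim_sv_dataset <- function(seed = 1, coverage = 60) {
  genome <- sim_genome(c(60000, 20000, 20000), gc = 0.45,
                       seed = derive_seed(seed, 1))
  events <- tibble(
    type = c("DEL", "DUP", "INV", "TRA"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(10000L, 25000L, 40000L, 12000L),
    size = c(500L, 1000L, 2000L, 0L),
    hom_len = c(4L, 0L, 0L, 0L),
    chrom2 = c(NA, NA, NA, "chr3"),
    pos2 = c(NA, NA, NA, 8000L),
    zygosity = "het"
  )
  pl <- sim_plant_svs(genome, events, seed = derive_seed(seed, 2))
  aln <- sim_reads(
    haplotypes = list(pl$reference, pl$mutated),
    segment_maps = list(NULL, pl$segments),
    coverage = coverage, read_len = 100, frag_mean = 300, frag_sd = 30,
    error_rate = 0.01, seed = derive_seed(seed, 3))
  list(reference = pl$reference, truth = pl$truth, aln = aln,
       events = events, segments = pl$segments)
}
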