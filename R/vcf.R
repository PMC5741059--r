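# VCFv4.2 break-end (BND) output. Every breakpoint is written as a pair of
# BND records linked by MATEID, with untemplated inserted sequence embedded
# in the bracketed ALT allele; single break-ends use the unpaired notation
# (`t.` / `.t`). Microhomology is reported through CIPOS/HOMLEN/HOMSEQ and
# inexact homology through the nonstandard IHOMPOS field.

vcf_header <- function(ref_lengths) {
  c("##fileformat=VCFv4.2",
    "##source=breakendr",
    sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
            as.integer(ref_lengths)),
    "##ALT=<ID=BND,Description=\"Break-end\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"ID of mate break-end\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"ID of the associated event\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=HOMLEN,Number=.,Type=Integer,Description=\"Length of breakpoint microhomology\">",
    "##INFO=<ID=HOMSEQ,Number=.,Type=String,Description=\"Sequence of breakpoint microhomology\">",
    "##INFO=<ID=IHOMPOS,Number=2,Type=Integer,Description=\"Interval of inexact homology around POS\">",
    "##INFO=<ID=SRC,Number=1,Type=Integer,Description=\"Split-read support count\">",
    "##INFO=<ID=DPC,Number=1,Type=Integer,Description=\"Discordant read-pair support count\">",
    "##INFO=<ID=ASC,Number=1,Type=Integer,Description=\"Assembly support count\">",
    "##INFO=<ID=SRQ,Number=1,Type=Float,Description=\"Split-read support quality\">",
    "##INFO=<ID=DPQ,Number=1,Type=Float,Description=\"Discordant read-pair support quality\">",
    "##INFO=<ID=ASQ,Number=1,Type=Float,Description=\"Assembly support quality\">",
    "##INFO=<ID=ASSEMBLY_SIDES,Number=1,Type=Integer,Description=\"Break-ends with assembly support (0-2)\">",
    "##INFO=<ID=SUPPORT_CAT,Number=.,Type=String,Description=\"Per-category support as category:count:quality\">",
    "##FILTER=<ID=LOW_QUAL,Description=\"Below the high-confidence thresholds\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

ref_base_at <- function(reference, chrom, pos) {
  L <- nchar(reference[chrom])
  p <- min(max(1, pos), L)
  substr(reference[chrom], p, p)
}

# ALT allele of one BND record. `unt_self_first` is the untemplated sequence
# in the derived orientation that reads this break-end's retained side first.
bnd_alt <- function(t, dir_self, partner_chrom, partner_pos, partner_dir,
                    unt_self_first) {
  p <- sprintf("%s:%d", partner_chrom, as.integer(partner_pos))
  br <- if (dir_self == "+") {
    if (partner_dir == "-") sprintf("[%s[", p) else sprintf("]%s]", p)
  } else {
    if (partner_dir == "+") sprintf("]%s]", p) else sprintf("[%s[", p)
  }
  unt <- if (is.na(unt_self_first)) "" else unt_self_first
  if (dir_self == "+") paste0(t, unt, br)
  else paste0(br, if (nzchar(unt)) revcomp(unt) else "", t)
}

info_str <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  paste(vapply(names(kv), function(k) {
    v <- kv[[k]]
    if (is.logical(v)) k else paste0(k, "=", paste(v, collapse = ","))
  }, character(1)), collapse = ";")
}

#' Write structural variant calls as a VCFv4.2 file
#'
#' @param calls Annotated call tibble (see [sv_call()]); needs `chrom_l`,
#'   `pos_l`, `dir_l`, `chrom_h`, `pos_h`, `dir_h`, `qual`, `confidence`,
#'   homology columns and the support breakdown columns.
#' @param reference Named character vector of chromosome sequences.
#' @param path Output VCF path.
#' @param single_breakends Optional tibble of unpartnered break-ends
#'   (`chrom_l`, `pos_l`, `dir_l`, `qual`, `untemplated`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, reference, path, single_breakends = NULL) {
  ref_lengths <- setNames(nchar(reference), names(reference))
  lines <- vcf_header(ref_lengths)
  fmt_num <- function(x) {
    ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
           sprintf("%.2f", x))
  }
  n <- if (is.null(calls)) 0 else nrow(calls)
  for (i in seq_len(n)) {
    cl <- calls[i, ]
    id_a <- sprintf("BND_%05d_1", i)
    id_b <- sprintf("BND_%05d_2", i)
    ev <- sprintf("EVENT_%05d", i)
    unt <- if ("untemplated" %in% names(cl) && !is.na(cl$untemplated))
      cl$untemplated else ""
    t_a <- ref_base_at(reference, cl$chrom_l, cl$pos_l)
    t_b <- ref_base_at(reference, cl$chrom_h, cl$pos_h)
    alt_a <- bnd_alt(t_a, cl$dir_l, cl$chrom_h, cl$pos_h, cl$dir_h, unt)
    alt_b <- bnd_alt(t_b, cl$dir_h, cl$chrom_l, cl$pos_l, cl$dir_l,
                     if (nzchar(unt)) revcomp(unt) else "")
    has_hom <- !is.na(cl$homlen)
    common <- function(mate) info_str(
      SVTYPE = "BND", MATEID = mate, EVENT = ev,
      CIPOS = c(as.integer(cl$cipos_lo), as.integer(cl$cipos_hi)),
      HOMLEN = if (has_hom) as.integer(cl$homlen) else NULL,
      HOMSEQ = if (has_hom && nzchar(cl$homseq)) cl$homseq else NULL,
      IHOMPOS = if (!is.na(cl$ihom_lo))
        c(as.integer(cl$ihom_lo), as.integer(cl$ihom_hi)) else NULL,
      SRC = as.integer(cl$n_sr), DPC = as.integer(cl$n_dp),
      ASC = as.integer(cl$n_as),
      SRQ = fmt_num(cl$q_sr), DPQ = fmt_num(cl$q_dp), ASQ = fmt_num(cl$q_as),
      ASSEMBLY_SIDES = as.integer(cl$assembly_sides),
      SUPPORT_CAT = cl$support_cat
    )
    filt <- if (cl$confidence == "HIGH") "PASS" else "LOW_QUAL"
    lines <- c(lines,
      sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
              cl$chrom_l, as.integer(cl$pos_l), id_a, t_a, alt_a,
              fmt_num(cl$qual), filt, common(id_b)),
      sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
              cl$chrom_h, as.integer(cl$pos_h), id_b, t_b, alt_b,
              fmt_num(cl$qual), filt, common(id_a)))
  }
  nsb <- if (is.null(single_breakends)) 0 else nrow(single_breakends)
  for (i in seq_len(nsb)) {
    sb <- single_breakends[i, ]
    t <- ref_base_at(reference, sb$chrom_l, sb$pos_l)
    unt <- if (!is.na(sb$untemplated)) sb$untemplated else ""
    alt <- if (sb$dir_l == "+") paste0(t, unt, ".")
    else paste0(".", if (nzchar(unt)) revcomp(unt) else "", t)
    lines <- c(lines, sprintf(
      "%s\t%d\tBNDU_%05d\t%s\t%s\t%s\tLOW_QUAL\t%s",
      sb$chrom_l, as.integer(sb$pos_l), i, t, alt, fmt_num(sb$qual),
      info_str(SVTYPE = "BND")))
  }
  # body sorted by coordinate
  hdr_n <- length(vcf_header(ref_lengths))
  body <- lines[-seq_len(hdr_n)]
  if (length(body) > 0) {
    ch <- sub("\t.*", "", body)
    po <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2))
    body <- body[order(match(ch, names(ref_lengths)), po)]
  }
  writeLines(c(lines[seq_len(hdr_n)], body), path)
  invisible(path)
}

#' Parse a break-end VCF written by [write_vcf()]
#'
#' Light-weight reader used for round-tripping: returns one row per BND
#' record with position, direction, partner and homology fields.
#'
#' @param path VCF path.
#' @return Tibble of break-end records.
#' @export
read_vcf_breakends <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0) {
    return(tibble(chrom = character(0), pos = integer(0), id = character(0),
                  alt = character(0), qual = numeric(0), dir = character(0),
                  partner_chrom = character(0), partner_pos = integer(0),
                  partner_dir = character(0),
                  mateid = character(0), homlen = integer(0),
                  cipos_lo = integer(0), cipos_hi = integer(0),
                  untemplated = character(0)))
  }
  f <- strsplit(ln, "\t")
  get_info <- function(info, key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    m
  }
  alt <- vapply(f, `[`, character(1), 5)
  info <- vapply(f, `[`, character(1), 8)
  parsed <- lapply(alt, function(a) {
    has_bracket <- grepl("[", a, fixed = TRUE) || grepl("]", a, fixed = TRUE)
    if (substr(a, 1, 1) %in% c("[", "]")) {
      # bracket-first form: [p[UNTt or ]p]UNTt  -> this break-end faces left
      m <- stringr::str_match(a, "^([\\[\\]])([^\\[\\]:]+):(\\d+)[\\[\\]](.*)$")
      if (is.na(m[1, 1])) return(list(dir = NA, pc = NA, pp = NA, pd = NA,
                                      unt = NA))
      tail_seg <- m[1, 5]
      unt_rec <- substr(tail_seg, 1, nchar(tail_seg) - 1)
      list(dir = "-", pc = m[1, 3], pp = as.integer(m[1, 4]),
           pd = if (m[1, 2] == "[") "-" else "+",
           unt = if (nzchar(unt_rec)) revcomp(unt_rec) else "")
    } else if (has_bracket) {
      # t-first form: tUNT[p[ or tUNT]p]  -> this break-end faces right
      m <- stringr::str_match(a, "^(.)(.*?)([\\[\\]])([^\\[\\]:]+):(\\d+)[\\[\\]]$")
      if (is.na(m[1, 1])) return(list(dir = NA, pc = NA, pp = NA, pd = NA,
                                      unt = NA))
      list(dir = "+", pc = m[1, 5], pp = as.integer(m[1, 6]),
           pd = if (m[1, 4] == "[") "-" else "+",
           unt = m[1, 3])
    } else {
      list(dir = NA, pc = NA, pp = NA, pd = NA, unt = NA)  # single break-end
    }
  })
  dir <- vapply(parsed, function(p) as.character(p$dir), character(1))
  pdir <- vapply(parsed, function(p) as.character(p$pd), character(1))
  cip <- strsplit(get_info(info, "CIPOS"), ",")
  unt <- vapply(parsed, function(p) as.character(p$unt), character(1))
  tibble(
    chrom = vapply(f, `[`, character(1), 1),
    pos = as.integer(vapply(f, `[`, character(1), 2)),
    id = vapply(f, `[`, character(1), 3),
    alt = alt,
    qual = as.numeric(vapply(f, `[`, character(1), 6)),
    dir = dir,
    partner_chrom = vapply(parsed, function(p) as.character(p$pc),
                           character(1)),
    partner_pos = vapply(parsed, function(p) {
      if (is.na(p$pp)) NA_integer_ else as.integer(p$pp)
    }, integer(1)),
    partner_dir = pdir,
    mateid = get_info(info, "MATEID"),
    homlen = as.integer(get_info(info, "HOMLEN")),
    cipos_lo = as.integer(vapply(cip, function(x)
      if (length(x)) x[1] else NA_character_, character(1))),
    cipos_hi = as.integer(vapply(cip, function(x)
      if (length(x) > 1) x[2] else NA_character_, character(1))),
    untemplated = unt
  )
}
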