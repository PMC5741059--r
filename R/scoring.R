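# Phred-scaled probabilistic evidence scoring.
#
# Every piece of evidence r is scored as the Phred-scaled probability of
# observing r without any underlying structural variant:
#   Pr(r) = Pr(M) Pr(r|M) + Pr(Mbar) * 1
# where M is the event that the mapping is correct,
#   Pr(M) = (1 - 10^(-mapq_a/10)) (1 - 10^(-mapq_b/10))
# (single-locus evidence uses mapq_a only), and Pr(r|M) is read off the
# relevant empirical library distribution:
#   split reads / soft clips: P_sc(l_sc), the soft-clip length tail mass
#   indel reads:              the matching I/D operation-length tail mass
#   read pairs:               p_d + (1 - p_d) P_rp(ifs)
#   one-end anchors:          p_u (no fragment size exists)
# Mismapped evidence is uninformative: Pr(r|Mbar) = 1.

# probability both mappings are correct
pr_mapping <- function(mapq_a, mapq_b = NULL) {
  p <- 1 - phred_inv(mapq_a)
  if (!is.null(mapq_b)) p <- p * (1 - phred_inv(mapq_b))
  p
}

# Upper tail mass P(L >= value) of an empirical distribution tibble(value,
# prob). Unseen / zero-mass values get a floor of 1/(2 n_obs).
tail_mass_upper <- function(dist, value, n_obs) {
  floor_mass <- if (n_obs > 0) 1 / (2 * n_obs) else 1
  if (is.null(dist) || nrow(dist) == 0) return(rep(1, length(value)))
  vapply(value, function(v) {
    m <- sum(dist$prob[dist$value >= v])
    max(m, floor_mass)
  }, numeric(1))
}

# Two-sided tail mass P(|L - med| >= |value - med|) around the distribution
# median; used for fragment sizes where both tails support an SV.
tail_mass_two_sided <- function(dist, value, n_obs) {
  floor_mass <- if (n_obs > 0) 1 / (2 * n_obs) else 1
  if (is.null(dist) || nrow(dist) == 0) return(rep(1, length(value)))
  med <- weighted_median(dist$value, dist$prob)
  vapply(value, function(v) {
    m <- sum(dist$prob[abs(dist$value - med) >= abs(v - med)])
    max(m, floor_mass)
  }, numeric(1))
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  x[which(cumsum(w) >= 0.5)[1]]
}

#' Positional de Bruijn graph k-mer weight
#'
#' The Phred-scaled joint probability that every base of the k-mer was called
#' correctly by the sequencer and that the aligner mapped the read to the
#' correct location:
#' `w = -10 log10(1 - (1 - 10^(-mapq/10)) prod_j (1 - 10^(-baseq_j/10)))`.
#'
#' @param baseq Integer vector of the k base qualities covered by the k-mer.
#' @param mapq Mapping quality of the read.
#' @param q_max Score cap (default 100).
#' @return Non-negative weight (Phred scale).
#' @examples
#' kmer_weight(10, 10) # ~7.21
#' @export
kmer_weight <- function(baseq, mapq, q_max = 100) {
  p_ok <- (1 - phred_inv(mapq)) * prod(1 - phred_inv(baseq))
  phred(1 - p_ok, q_max = q_max)
}

# Rolling per-k-mer weights for a whole read: product of base-correct
# probabilities over each window of k quals, times the mapping term.
kmer_weights_read <- function(baseq, mapq, k, q_max = 100) {
  n <- length(baseq)
  if (n < k) return(numeric(0))
  lp <- log10(1 - phred_inv(baseq))
  cs <- c(0, cumsum(lp))
  win <- cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]
  p_ok <- (1 - phred_inv(mapq)) * 10^win
  pmin(-10 * log10(1 - p_ok), q_max)
}

combine_score <- function(pr_m, pr_r_given_m, q_max = 100) {
  phred(pr_m * pr_r_given_m + (1 - pr_m), q_max = q_max)
}

#' Score split-read or soft-clip evidence
#'
#' `Pr(r|M) = P_sc(l_sc)`, the library soft-clip length tail mass at the
#' observed clip length (measured before split-read identification).
#'
#' @param l_sc Soft-clip length in bp.
#' @param mapq_a,mapq_b Mapping qualities of the two loci (`mapq_b = NULL` for
#'   single-locus soft clips).
#' @param metrics A library metrics object (see [collect_metrics()]).
#' @param q_max Score cap.
#' @return Phred score of the evidence arising without an SV.
#' @export
score_split_read <- function(l_sc, mapq_a, mapq_b = NULL, metrics, q_max = 100) {
  pm <- pr_mapping(mapq_a, mapq_b)
  psc <- tail_mass_upper(metrics$softclip_len_dist, l_sc, metrics$n_softclips)
  combine_score(pm, psc, q_max)
}

#' Score discordant read-pair or one-end-anchor evidence
#'
#' Discordant pairs: `Pr(r|M) = p_d + (1 - p_d) P_rp(ifs)` where `p_d` is the
#' chimeric-fragment rate and `P_rp` the two-sided fragment-size tail mass.
#' One-end anchors have no inferred fragment size; they use `p_u` (the rate of
#' pairs with exactly one read unmapped) with the fragment term omitted, and
#' only the mapped read's mapping quality.
#'
#' @param ifs Inferred fragment size (bp); ignored for `kind = "ONE_END_ANCHOR"`.
#' @param mapq_a,mapq_b Mapping qualities (`mapq_b` omitted for OEA).
#' @param metrics Library metrics object.
#' @param kind `"DISCORDANT_PAIR"` or `"ONE_END_ANCHOR"`.
#' @param q_max Score cap.
#' @return Phred score.
#' @export
score_read_pair <- function(ifs, mapq_a, mapq_b = NULL, metrics,
                            kind = c("DISCORDANT_PAIR", "ONE_END_ANCHOR"),
                            q_max = 100) {
  kind <- match.arg(kind)
  if (kind == "ONE_END_ANCHOR") {
    pm <- pr_mapping(mapq_a)
    return(combine_score(pm, metrics$p_u, q_max))
  }
  if (is.null(metrics$fragment_size_dist) || nrow(metrics$fragment_size_dist) == 0) {
    abort("no fragment size distribution available for discordant-pair scoring")
  }
  pm <- pr_mapping(mapq_a, mapq_b)
  prp <- tail_mass_two_sided(metrics$fragment_size_dist, ifs, metrics$n_fragments)
  combine_score(pm, metrics$p_d + (1 - metrics$p_d) * prp, q_max)
}

#' Score an indel-containing read
#'
#' Scored as a split read, but with the soft-clip length distribution replaced
#' by the matching insertion or deletion CIGAR operation-length distribution.
#'
#' @param op `"I"` or `"D"`.
#' @param len Operation length (bp).
#' @param mapq Mapping quality of the read (one alignment spans the indel).
#' @param metrics Library metrics object.
#' @param q_max Score cap.
#' @return Phred score.
#' @export
score_indel_read <- function(op, len, mapq, metrics, q_max = 100) {
  dist <- if (op == "I") metrics$insertion_len_dist else metrics$deletion_len_dist
  n <- if (op == "I") metrics$n_insertions else metrics$n_deletions
  pm <- pr_mapping(mapq)
  combine_score(pm, tail_mass_upper(dist, len, n), q_max)
}

#' Score a break-end assembly from its constituent reads
#'
#' Constituent soft-clipped reads are promoted to split reads and constituent
#' one-end-anchor reads to discordant pairs within the context of the assembly:
#' the anchored mapping quality is the greatest constituent mapping quality and
#' the unanchored mapping quality is the assembly realignment mapping quality
#' (promoted one-end anchors keep `p_u` in place of `p_d`). The assembly score
#' is the maximum of the promoted constituent Phred terms.
#'
#' @param constituents Tibble of supporting evidence with columns `kind`,
#'   `mapq_a`, `l_sc`, `ifs`.
#' @param realign_mapq Mapping quality of the assembly realignment.
#' @param metrics Library metrics object.
#' @param q_max Score cap.
#' @return Phred score of the assembly.
#' @export
score_assembly <- function(constituents, realign_mapq, metrics, q_max = 100) {
  if (nrow(constituents) == 0) abort("assembly has an empty support set")
  mapq_a <- max(constituents$mapq_a)
  terms <- purrr::pmap_dbl(
    constituents[, c("kind", "l_sc", "ifs")],
    function(kind, l_sc, ifs) {
      if (kind %in% c("SOFT_CLIP", "SPLIT_READ", "INDEL")) {
        score_split_read(l_sc, mapq_a, realign_mapq, metrics, q_max)
      } else if (kind == "ONE_END_ANCHOR") {
        # promoted to DP, p_u in place of p_d, no fragment term
        pm <- pr_mapping(mapq_a, realign_mapq)
        combine_score(pm, metrics$p_u, q_max)
      } else {
        score_read_pair(ifs, mapq_a, realign_mapq, metrics,
                        kind = "DISCORDANT_PAIR", q_max = q_max)
      }
    }
  )
  max(terms)
}

#' Score a table of extracted evidence
#'
#' Adds a Phred score column `q` to an evidence tibble, dispatching on `kind`.
#'
#' @param evidence Evidence tibble from [extract_evidence()].
#' @param metrics A single metrics object or a named list keyed by
#'   `library_id`.
#' @param q_max Score cap.
#' @return The evidence tibble with a `q` column.
#' @export
score_evidence <- function(evidence, metrics, q_max = 100) {
  if (nrow(evidence) == 0) return(dplyr::mutate(evidence, q = numeric(0)))
  get_metrics <- function(lib) {
    if (!is.null(metrics$fragment_size_dist) || inherits(metrics, "sv_metrics"))
      return(metrics)
    metrics[[lib]]
  }
  evidence$q <- purrr::pmap_dbl(
    evidence[, c("kind", "library_id", "l_sc", "ifs", "mapq_a", "mapq_b",
                 "indel_op", "indel_len")],
    function(kind, library_id, l_sc, ifs, mapq_a, mapq_b, indel_op, indel_len) {
      m <- get_metrics(library_id)
      switch(kind,
        SOFT_CLIP = score_split_read(l_sc, mapq_a, NULL, m, q_max),
        SPLIT_READ = score_split_read(l_sc, mapq_a, mapq_b, m, q_max),
        INDEL = score_indel_read(indel_op, indel_len, mapq_a, m, q_max),
        DISCORDANT_PAIR = score_read_pair(ifs, mapq_a, mapq_b, m,
                                          "DISCORDANT_PAIR", q_max),
        ONE_END_ANCHOR = score_read_pair(NA_real_, mapq_a, NULL, m,
                                         "ONE_END_ANCHOR", q_max)
      )
    }
  )
  evidence
}
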