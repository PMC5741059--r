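#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join inner_join anti_join n row_number desc across
#'   first last lag lead distinct slice pull rename count if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn inform
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr map_lgl keep discard
#' @importFrom stats median mad setNames quantile rnorm runif rbinom
#' @importFrom utils head tail
#' @useDynLib breakendr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Base codes: A=0, C=1, G=2, T=3; anything else is NA (k-mers containing
# ambiguous bases are skipped).
.BASE_CODE <- local({
  x <- rep(NA_integer_, 256)
  x[utf8ToInt("A")] <- 0L; x[utf8ToInt("a")] <- 0L
  x[utf8ToInt("C")] <- 1L; x[utf8ToInt("c")] <- 1L
  x[utf8ToInt("G")] <- 2L; x[utf8ToInt("g")] <- 2L
  x[utf8ToInt("T")] <- 3L; x[utf8ToInt("t")] <- 3L
  x
})
.BASES <- c("A", "C", "G", "T")

#' Encode the k-mers of a sequence as numeric codes
#'
#' Packs each k-mer into a double using 2 bits per base (A=0, C=1, G=2, T=3).
#' Doubles represent integers exactly below 2^53, which bounds k at 26.
#' K-mers containing ambiguous bases yield `NA`.
#'
#' @param seq A character scalar of DNA bases.
#' @param k K-mer size (4--26).
#' @return Numeric vector of length `nchar(seq) - k + 1` (length 0 if the
#'   sequence is shorter than `k`).
#' @examples
#' kmer_codes("ACGT", 2)
#' @export
kmer_codes <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (k < 2 || k > 26) abort("k must be between 2 and 26")
  d <- .BASE_CODE[utf8ToInt(seq)]
  n <- length(d)
  if (n < k) return(numeric(0))
  # rolling polynomial in base 4
  dd <- d
  dd[is.na(dd)] <- 0L
  pw <- 4^(seq_len(k) - 1)
  code <- numeric(n - k + 1)
  acc <- sum(dd[1:k] * rev(pw))
  code[1] <- acc
  if (n > k) {
    top <- 4^(k - 1)
    for (i in 2:(n - k + 1)) {
      acc <- (acc - dd[i - 1] * top) * 4 + dd[i + k - 1]
      code[i] <- acc
    }
  }
  bad <- is.na(d)
  if (any(bad)) {
    cs <- cumsum(bad)
    # k-mer i covers bases i..i+k-1
    idx <- seq_len(n - k + 1)
    nbad <- cs[idx + k - 1] - c(0, cs)[idx]
    code[nbad > 0] <- NA_real_
  }
  code
}

#' Decode a k-mer code back to its base string
#' @param code Numeric k-mer code(s) from [kmer_codes()].
#' @param k K-mer size used to encode.
#' @return Character vector of k-mer strings.
#' @export
kmer_string <- function(code, k) {
  vapply(code, function(cd) {
    if (is.na(cd)) return(NA_character_)
    out <- character(k)
    for (i in k:1) {
      out[i] <- .BASES[cd %% 4 + 1]
      cd <- cd %/% 4
    }
    paste(out, collapse = "")
  }, character(1))
}

# last base character of a k-mer code
kmer_last_base <- function(code) .BASES[code %% 4 + 1]
# code of last k-1 bases
kmer_suffix <- function(code, k) code %% (4^(k - 1))
# code of first k-1 bases
kmer_prefix <- function(code) code %/% 4

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Phred-scale a probability
#'
#' `Q = -10 log10(P)`, capped at `q_max` so that perfect probabilities do not
#' produce infinite scores.
#'
#' @param p Probability in `[0, 1]`.
#' @param q_max Cap applied to the returned score (default 100).
#' @return Non-negative Phred score.
#' @examples
#' phred(0.1)   # 10
#' phred(0.001) # 30
#' @export
phred <- function(p, q_max = 100) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("probability outside [0, 1]")
  pmin(-10 * log10(p), q_max)
}

#' Invert a Phred score to a probability
#' @param q Phred score.
#' @return Probability `10^(-q/10)`.
#' @export
phred_inv <- function(q) 10^(-q / 10)

# ---- CIGAR helpers -----------------------------------------------------------

# Parse CIGAR strings into a list of list(op = chr, len = int); "*" yields
# empty vectors. Plain lists, not tibbles: these run over every read.
cigar_ops <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  lapply(m, function(x) list(op = x[, 3], len = as.integer(x[, 2])))
}

# reference-consumed width of each CIGAR
cigar_ref_width <- function(cigar) {
  vapply(cigar_ops(cigar), function(x) {
    sum(x$len[x$op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

# leading / trailing soft clip lengths (vectorized regex)
cigar_clip <- function(cigar) {
  lead <- stringr::str_match(cigar, "^(\\d+)S")[, 2]
  trail <- stringr::str_match(cigar, "(\\d+)S$")[, 2]
  list(lead = ifelse(is.na(lead), 0L, as.integer(lead)),
       trail = ifelse(is.na(trail), 0L, as.integer(trail)))
}

# decode a SAM QUAL string into integer Phred scores ("*" -> NULL)
qual_ints <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q) || q == "*") return(integer(0))
    as.integer(charToRaw(q)) - 33L
  })
}

qual_string <- function(q) {
  if (!is.list(q)) q <- list(q)
  vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1))
}

# seed helper: derive a bounded child seed from a master seed and a tag
derive_seed <- function(seed, tag) {
  (as.integer(seed) * 1000003L + as.integer(tag)) %% .Machine$integer.max
}
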