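# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy library metrics into a long distribution tibble
#'
#' @param x An `sv_metrics` object.
#' @param ... Unused.
#' @return Tibble with `distribution`, `value`, `prob`.
#' @export
tidy.sv_metrics <- function(x, ...) {
  bind_rows(
    x$fragment_size_dist %>% mutate(distribution = "fragment_size"),
    x$softclip_len_dist %>% mutate(distribution = "softclip_len"),
    x$insertion_len_dist %>% mutate(distribution = "insertion_len"),
    x$deletion_len_dist %>% mutate(distribution = "deletion_len")
  ) %>% select("distribution", "value", "prob")
}

#' One-row summary of library metrics
#' @param x An `sv_metrics` object.
#' @param ... Unused.
#' @return One-row tibble of headline metrics.
#' @export
glance.sv_metrics <- function(x, ...) {
  tibble(
    library_id = x$library_id,
    total_reads = x$read_counts$total_reads,
    mapped_reads = x$read_counts$mapped_reads,
    total_pairs = x$read_counts$total_pairs,
    max_read_length = x$max_read_length,
    concordant_lo = x$concordant_lo,
    concordant_hi = x$concordant_hi,
    p_d = x$p_d,
    p_u = x$p_u
  )
}

#' Tidy a positional de Bruijn graph into its node table
#' @param x An `sv_graph`.
#' @param ... Unused.
#' @return Node tibble with decoded k-mers.
#' @export
tidy.sv_graph <- function(x, ...) {
  pg_nodes(x) %>% mutate(kmer = kmer_string(.data$code, x$k)) %>%
    select("pos", "kmer", "weight", "anchored", "n_support")
}

#' @export
glance.sv_graph <- function(x, ...) {
  nd <- pg_nodes(x)
  tibble(k = x$k, direction = x$direction, n_nodes = nrow(nd),
         n_reads = dplyr::n_distinct(x$support$read_id),
         total_weight = sum(nd$weight),
         n_anchored = sum(nd$anchored))
}

#' Tidy structural variant calls
#' @param x An `sv_result` from [sv_call()].
#' @param ... Unused.
#' @return The call tibble without list columns.
#' @export
tidy.sv_result <- function(x, ...) {
  x$calls %>% select(-dplyr::any_of("members"))
}

#' @export
glance.sv_result <- function(x, ...) {
  tibble(
    n_calls = nrow(x$calls),
    n_high = sum(x$calls$confidence == "HIGH"),
    n_single_breakends = if (is.null(x$single_breakends)) 0L
    else nrow(x$single_breakends),
    n_contigs = nrow(x$contigs),
    n_evidence = nrow(x$evidence),
    total_qual = sum(x$calls$qual)
  )
}

#' Plot a positional de Bruijn graph
#'
#' Nodes by position and weight, coloured by anchored status; useful for
#' inspecting assembly fixtures.
#'
#' @param object An `sv_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sv_graph <- function(object, ...) {
  nd <- pg_nodes(object)
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$pos, y = .data$weight,
                                   colour = .data$anchored)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "expected genomic position", y = "node weight (Phred)",
                  colour = "anchored") +
    ggplot2::theme_minimal()
}

#' Plot structural variant calls along the genome
#'
#' Lower break-end position against call quality, shaped by directional
#' class and coloured by confidence.
#'
#' @param object An `sv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sv_result <- function(object, ...) {
  cl <- object$calls %>%
    mutate(class = paste0(.data$dir_l, .data$dir_h))
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$pos_l, y = .data$qual,
                                   colour = .data$confidence,
                                   shape = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(. ~ .data$chrom_l, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "lower break-end position", y = "call quality (Phred)",
                  colour = "confidence", shape = "direction") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
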