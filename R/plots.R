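#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_errorbar
#'   geom_hline labs coord_flip theme_minimal scale_colour_manual
NULL

#' Plot bootstrap effect sizes with their percentile intervals
#'
#' One point per spot and contrast (differential spots highlighted), with
#' the bootstrap percentile interval as an error bar and the differential
#' threshold as dashed guides.
#'
#' @param object A `mito_diffexp` tibble from [bootstrap_effects()].
#' @param top Show only the `top` spots with largest |effect size| per
#'   contrast (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_diffexp <- function(object, top = 30, ...) {
  thr <- attr(object, "threshold") %||% 0.5
  df <- as_tibble(object) |>
    group_by(.data$contrast) |>
    arrange(desc(abs(.data$effect_size)), .by_group = TRUE) |>
    slice_head(n = top) |>
    ungroup()
  ggplot(df, aes(x = stats::reorder(.data$spot_id, .data$effect_size),
                 y = .data$effect_size, colour = .data$is_differential)) +
    geom_hline(yintercept = c(-thr, thr), linetype = "dashed", colour = "grey40") +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.3) +
    geom_point(size = 1.5) +
    coord_flip() +
    ggplot2::facet_wrap(~contrast, scales = "free_y") +
    scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey55"),
                        name = "differential") +
    labs(x = NULL, y = "bootstrap effect size (log2 fold change)") +
    theme_minimal()
}

#' Plot an overrepresentation result
#'
#' Dot plot of enrichment strength against terms, sized by annotated
#' overlap and coloured by FDR.
#'
#' @param object A `mito_enrichment` tibble from [enrich_sets()].
#' @param max_terms Terms shown, best first (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_enrichment <- function(object, max_terms = 20, ...) {
  df <- as_tibble(object) |>
    filter(.data$k > 0) |>
    arrange(.data$fdr) |>
    slice_head(n = max_terms)
  ggplot(df, aes(x = .data$strength,
                 y = stats::reorder(.data$term_id, -.data$fdr),
                 size = .data$k, colour = -log10(.data$fdr))) +
    geom_point() +
    labs(x = "strength, log10(observed/expected)", y = NULL,
         colour = "-log10 FDR", size = "overlap k") +
    theme_minimal()
}

#' Plot MCL cluster sizes
#'
#' @param object An `mcl_partition` from [mcl()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcl_partition <- function(object, ...) {
  df <- count(object$membership, .data$cluster)
  ggplot(df, aes(x = factor(.data$cluster), y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "cluster", y = "nodes") +
    theme_minimal()
}

#' Plot the opposite-regulation TF screen
#'
#' Bars of in-network target counts per TF with the opposite-regulated
#' fraction highlighted.
#'
#' @param object A `tf_screen` tibble from [screen_opposite_tfs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_screen <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("n_targets_in_network", "n_opposite_targets"),
                        names_to = "kind", values_to = "n") |>
    mutate(kind = ifelse(.data$kind == "n_opposite_targets",
                         "opposite-regulated", "in network"))
  ggplot(df, aes(x = stats::reorder(.data$tf_id, .data$n), y = .data$n,
                 fill = .data$kind)) +
    geom_col(position = "identity", alpha = 0.8) +
    coord_flip() +
    labs(x = NULL, y = "targets", fill = NULL) +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
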