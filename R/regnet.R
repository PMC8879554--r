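#' Extend a PPI network with TF-to-target regulatory edges
#'
#' Adds transcription-factor nodes and directed regulatory edges from a
#' linkset to a protein-protein interaction network. Only links whose
#' target is a network protein are used; TFs with no in-network target are
#' absent from the result. The PPI edge set is never modified, and
#' extending an already-extended network with the same linkset changes
#' nothing.
#'
#' @param network Undirected igraph PPI network, or an `extended_network`.
#' @param linkset Tibble with columns `tf`, `target` (e.g. from
#'   [read_linkset()] or [simulate_linkset()]).
#' @param node_effects Optional tidy effect table (`spot_id`, `contrast`,
#'   `effect_size`) attached for export and screening.
#' @return Object of class `extended_network`: list with `ppi` (the
#'   untouched PPI graph), `regulatory` (tibble `tf`, `target` of retained
#'   links), `tfs` (sorted TF ids) and `node_effects`.
#' @examples
#' g <- igraph::make_graph(~ A - B)
#' ext <- extend_regulatory(g, tibble::tibble(tf = "TF1", target = "A"))
#' ext$tfs
#' @export
extend_regulatory <- function(network, linkset, node_effects = NULL) {
  if (inherits(network, "extended_network")) {
    base <- network$ppi
    prior <- network$regulatory
    if (is.null(node_effects)) node_effects <- network$node_effects
  } else {
    if (!igraph::is_igraph(network) || igraph::vcount(network) == 0L) {
      stop_mitonet("`network` must be a non-empty igraph or extended_network.")
    }
    base <- network
    prior <- NULL
  }
  if (!all(c("tf", "target") %in% names(linkset))) {
    stop_mitonet("`linkset` needs columns `tf` and `target`.")
  }
  nodes <- igraph::V(base)$name
  kept <- linkset |>
    as_tibble() |>
    select("tf", "target") |>
    filter(.data$target %in% nodes) |>
    distinct()
  if (!is.null(prior)) kept <- distinct(bind_rows(prior, kept))
  structure(
    list(
      ppi = base,
      regulatory = arrange(kept, .data$tf, .data$target),
      tfs = sort(unique(kept$tf)),
      node_effects = node_effects
    ),
    class = "extended_network"
  )
}

#' @export
print.extended_network <- function(x, ...) {
  cat(sprintf(
    "Extended network: %d proteins, %d PPI edges, %d TFs, %d regulatory edges\n",
    igraph::vcount(x$ppi), igraph::ecount(x$ppi),
    length(x$tfs), nrow(x$regulatory)
  ))
  invisible(x)
}

#' Flatten an extended network into a single annotated graph
#'
#' Builds one directed igraph for export: PPI edges (kind `"ppi"`,
#' written once in arbitrary orientation) plus regulatory edges (kind
#' `"regulatory"`, TF to target). Vertices carry `kind`
#' (`"protein"`/`"tf"`), within-PPI `degree`, optional `cluster` ids and
#' one attribute per contrast with the node's effect size.
#'
#' @param extnet An `extended_network`.
#' @param partition Optional `mcl_partition` (or `node`/`cluster` tibble)
#'   used to annotate protein vertices.
#' @return A directed igraph.
#' @seealso [write_graphml()]
#' @export
as_annotated_graph <- function(extnet, partition = NULL) {
  if (!inherits(extnet, "extended_network")) {
    stop_mitonet("`extnet` must be an extended_network.")
  }
  ppi <- extnet$ppi
  proteins <- igraph::V(ppi)$name
  g <- igraph::make_empty_graph(n = length(proteins) + length(extnet$tfs),
                                directed = TRUE)
  igraph::V(g)$name <- c(proteins, extnet$tfs)
  igraph::V(g)$kind <- c(rep("protein", length(proteins)),
                         rep("tf", length(extnet$tfs)))
  el <- igraph::as_edgelist(ppi)
  ekind <- character(0)
  if (nrow(el)) {
    g <- igraph::add_edges(g, t(el))
    ekind <- rep("ppi", nrow(el))
  }
  if (nrow(extnet$regulatory)) {
    g <- igraph::add_edges(g, rbind(extnet$regulatory$tf, extnet$regulatory$target))
    ekind <- c(ekind, rep("regulatory", nrow(extnet$regulatory)))
  }
  igraph::E(g)$kind <- ekind
  w <- igraph::E(ppi)$weight
  igraph::E(g)$weight <- c(if (is.null(w)) rep(1, nrow(el)) else w,
                           rep(1, nrow(extnet$regulatory)))
  igraph::V(g)$degree <- c(igraph::degree(ppi), rep(0L, length(extnet$tfs)))
  if (!is.null(partition)) {
    if (inherits(partition, "mcl_partition")) partition <- partition$membership
    igraph::V(g)$cluster <- partition$cluster[match(igraph::V(g)$name, partition$node)]
  }
  if (!is.null(extnet$node_effects)) {
    eff <- as_tibble(extnet$node_effects)
    for (ctr in unique(eff$contrast)) {
      e <- eff[eff$contrast == ctr, ]
      attr_name <- paste0("logfc_", gsub("[^A-Za-z0-9]+", "_", ctr))
      g <- igraph::set_vertex_attr(
        g, attr_name, value = e$effect_size[match(igraph::V(g)$name, e$spot_id)]
      )
    }
  }
  g
}

#' Screen transcription factors for opposite-regulation targets
#'
#' Formalises the opposite-regulation screen: a target is "opposite" when
#' its effect sizes in the revascularization-vs-ischemia and
#' post-conditioning-vs-ischemia contrasts have opposite signs and both
#' magnitudes strictly exceed the threshold. A TF is a candidate when at
#' least one of its in-network targets is opposite. Targets lacking an
#' effect in either contrast are skipped with a warning, never treated as
#' zero.
#'
#' @param extnet An `extended_network`.
#' @param effects Tidy effect table (`spot_id`, `contrast`, `effect_size`);
#'   defaults to the table attached to `extnet`.
#' @param contrast_a,contrast_b The two contrast labels to compare
#'   (defaults `"I/R vs Isch"` and `"PostC vs Isch"`).
#' @param threshold Positive magnitude threshold (default 0.5, strict).
#' @return Tibble of class `tf_screen`, one row per TF: `tf_id`,
#'   `n_targets_in_network`, `n_opposite_targets`, `opposite_targets`
#'   (list-column), `is_opposite_candidate`; sorted by
#'   `n_opposite_targets` descending, then `tf_id`.
#' @export
screen_opposite_tfs <- function(extnet,
                                effects = extnet$node_effects,
                                contrast_a = "I/R vs Isch",
                                contrast_b = "PostC vs Isch",
                                threshold = 0.5) {
  if (!inherits(extnet, "extended_network")) {
    stop_mitonet("`extnet` must be an extended_network.")
  }
  check_scalar_number(threshold, "threshold", min = 0, strict_min = TRUE)
  if (is.null(effects)) {
    stop_mitonet("`effects` must be supplied (spot_id, contrast, effect_size).")
  }
  effects <- as_tibble(effects)
  for (ctr in c(contrast_a, contrast_b)) {
    if (!ctr %in% effects$contrast) {
      stop_mitonet(sprintf("contrast '%s' not found in `effects`.", ctr))
    }
  }
  wide <- effects |>
    filter(.data$contrast %in% c(contrast_a, contrast_b)) |>
    tidyr::pivot_wider(id_cols = "spot_id", names_from = "contrast",
                       values_from = "effect_size")
  targets <- unique(extnet$regulatory$target)
  known <- wide$spot_id[!is.na(wide[[contrast_a]]) & !is.na(wide[[contrast_b]])]
  skipped <- setdiff(targets, known)
  if (length(skipped)) {
    rlang::warn(sprintf(
      "%d target(s) lack an effect size in one of the contrasts and were skipped: %s%s",
      length(skipped), paste(utils::head(skipped, 5), collapse = ", "),
      if (length(skipped) > 5) ", ..." else ""
    ))
  }
  opp_tbl <- wide |>
    filter(.data$spot_id %in% known) |>
    mutate(opposite = sign(.data[[contrast_a]]) != sign(.data[[contrast_b]]) &
             abs(.data[[contrast_a]]) > threshold &
             abs(.data[[contrast_b]]) > threshold)
  opp_nodes <- opp_tbl$spot_id[opp_tbl$opposite]
  out <- extnet$regulatory |>
    group_by(tf_id = .data$tf) |>
    summarise(
      n_targets_in_network = n_distinct(.data$target),
      opposite_targets = list(sort(intersect(.data$target, opp_nodes))),
      .groups = "drop"
    ) |>
    mutate(
      n_opposite_targets = lengths(.data$opposite_targets),
      is_opposite_candidate = .data$n_opposite_targets > 0L
    ) |>
    select("tf_id", "n_targets_in_network", "n_opposite_targets",
           "opposite_targets", "is_opposite_candidate") |>
    arrange(desc(.data$n_opposite_targets), .data$tf_id)
  class(out) <- c("tf_screen", class(out))
  out
}

#' Write TF screen candidates as TSV
#'
#' @param screen Tibble from [screen_opposite_tfs()].
#' @param path Output path.
#' @param header Extra metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_tf_screen <- function(screen, path, header = character()) {
  flat <- as_tibble(screen) |>
    mutate(opposite_target_ids = vapply(
      .data$opposite_targets, paste, "", collapse = ";"
    )) |>
    select("tf_id", "n_targets_in_network", "n_opposite_targets",
           "opposite_target_ids", "is_opposite_candidate")
  write_tsv_atomic(flat, path, header = header)
}
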