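#' Induce the differential-protein network from a background interactome
#'
#' Takes the subgraph of the background interactome induced on a node set.
#' Nodes of the set absent from the background are retained as isolates
#' (and reported via a warning), so the result always has one vertex per
#' requested node. Each vertex carries its within-subgraph degree as the
#' `degree` attribute.
#'
#' @param background Undirected igraph interactome.
#' @param node_set Character vector of node identifiers (non-empty).
#' @return An igraph over `node_set` with edge weights inherited from the
#'   background and a `degree` vertex attribute.
#' @export
induce_network <- function(background, node_set) {
  if (length(node_set) == 0L) stop_mitonet("`node_set` must be non-empty.")
  node_set <- unique(as.character(node_set))
  bg_nodes <- igraph::V(background)$name
  present <- intersect(node_set, bg_nodes)
  missing <- setdiff(node_set, bg_nodes)
  if (length(present) == 0L) {
    rlang::warn("no node of `node_set` is present in the background; returning isolates only.")
    g <- igraph::make_empty_graph(n = length(node_set), directed = FALSE)
    igraph::V(g)$name <- node_set
  } else {
    g <- igraph::induced_subgraph(background, present)
    if (length(missing)) {
      rlang::warn(sprintf(
        "%d node(s) absent from the background kept as isolates: %s%s",
        length(missing), paste(utils::head(missing, 5), collapse = ", "),
        if (length(missing) > 5) ", ..." else ""
      ))
      g <- igraph::add_vertices(g, length(missing), name = missing)
    }
  }
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Permutation test of PPI enrichment
#'
#' Tests whether a node set is more densely connected in a background
#' interactome than same-sized node sets drawn at random: the observed
#' statistic is the edge count of the induced subgraph, the null
#' distribution is built by drawing `n_permutations` uniform node sets of
#' the same size (or degree-matched sets), and the p-value is the standard
#' permutation estimate `(1 + #(null >= observed)) / (n_permutations + 1)`.
#'
#' @param background Undirected igraph interactome.
#' @param node_set Character vector of node identifiers; those absent from
#'   the background are ignored for edge counting but still count towards
#'   the sampled set size.
#' @param n_permutations Number of null draws (>= 100).
#' @param seed Integer RNG seed.
#' @param null Null sampling scheme: `"uniform"` node sets (default) or
#'   `"degree"`-matched sets (each observed node replaced by a random node
#'   from the same degree decile).
#' @return Object of class `ppi_enrichment`: list with `observed_edges`,
#'   `null_mean`, `p_value`, `n_permutations`, `n_nodes`, `null_scheme`.
#' @examples
#' sim <- simulate_interactome(network_sim_config(c(8, rep(1, 40)),
#'                                                p_within = 1, p_between = 0.05,
#'                                                seed = 3))
#' clique <- sim$membership$node[sim$membership$cluster == 1]
#' ppi_enrichment(sim$graph, clique, n_permutations = 200, seed = 1)
#' @export
ppi_enrichment <- function(background, node_set, n_permutations = 1000,
                           seed = 1L, null = c("uniform", "degree")) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 100L)
  null <- match.arg(null)
  node_set <- unique(as.character(node_set))
  bg_nodes <- igraph::V(background)$name
  n_bg <- length(bg_nodes)
  if (length(node_set) > n_bg) {
    stop_mitonet("`node_set` is larger than the background network.")
  }
  k <- length(node_set)
  # dense logical adjacency is much faster to index at the network sizes
  # this test meets; fall back to sparse only for very large backgrounds
  A <- if (n_bg <= 3000) {
    igraph::as_adjacency_matrix(background, sparse = FALSE) > 0
  } else {
    igraph::as_adjacency_matrix(background, sparse = TRUE) > 0
  }
  idx_obs <- match(intersect(node_set, bg_nodes), bg_nodes)
  observed <- count_induced_edges(A, idx_obs)
  deg <- igraph::degree(background)
  null_counts <- withr::with_seed(seed, {
    if (null == "uniform") {
      vapply(seq_len(n_permutations), function(i) {
        count_induced_edges(A, sample.int(n_bg, k))
      }, numeric(1))
    } else {
      bins <- degree_bins(deg)
      obs_bins <- bins[idx_obs]
      vapply(seq_len(n_permutations), function(i) {
        count_induced_edges(A, sample_degree_matched(bins, obs_bins))
      }, numeric(1))
    }
  })
  structure(
    list(
      observed_edges = observed,
      null_mean = mean(null_counts),
      p_value = (1 + sum(null_counts >= observed)) / (n_permutations + 1),
      n_permutations = n_permutations,
      n_nodes = k,
      null_scheme = null
    ),
    class = "ppi_enrichment"
  )
}

count_induced_edges <- function(A, idx) {
  if (length(idx) < 2L) return(0)
  sum(A[idx, idx]) / 2
}

degree_bins <- function(deg) {
  brk <- unique(stats::quantile(deg, probs = seq(0, 1, 0.1)))
  if (length(brk) < 2L) return(rep(1L, length(deg)))
  as.integer(cut(deg, breaks = brk, include.lowest = TRUE))
}

# one degree-matched null set: for each observed node's degree bin, draw a
# distinct node from the same bin
sample_degree_matched <- function(bins, obs_bins) {
  out <- integer(length(obs_bins))
  used <- logical(length(bins))
  for (i in seq_along(obs_bins)) {
    cand <- which(bins == obs_bins[i] & !used)
    if (length(cand) == 0L) cand <- which(!used)
    pick <- cand[sample.int(length(cand), 1L)]
    out[i] <- pick
    used[pick] <- TRUE
  }
  out
}

#' @export
print.ppi_enrichment <- function(x, ...) {
  cat(sprintf(
    "PPI enrichment: %d nodes, %g observed edges vs %.2f expected (%s null, %d permutations), p = %.4g\n",
    x$n_nodes, x$observed_edges, x$null_mean, x$null_scheme,
    x$n_permutations, x$p_value
  ))
  invisible(x)
}

#' @rdname glance.ppi_enrichment
#' @export
tidy.ppi_enrichment <- function(x, ...) glance.ppi_enrichment(x, ...)

#' One-row summary of a PPI-enrichment test
#'
#' @param x A `ppi_enrichment` object.
#' @param ... Unused.
#' @return Tibble with `n_nodes`, `observed_edges`, `null_mean`, `p_value`,
#'   `n_permutations`, `null_scheme`.
#' @export
glance.ppi_enrichment <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes,
    observed_edges = x$observed_edges,
    null_mean = x$null_mean,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    null_scheme = x$null_scheme
  )
}

#' Write a PPI-enrichment result as JSON
#'
#' JSON carries a `meta` object (tool version, seed, configuration hash)
#' instead of comment lines, which JSON does not allow.
#'
#' @param x A `ppi_enrichment` object.
#' @param path Output path.
#' @param meta Named list of metadata fields.
#' @return `path`, invisibly.
#' @export
write_enrichment_json <- function(x, path, meta = list()) {
  payload <- list(
    meta = c(list(tool = "mitonet", version = pkg_version()), meta),
    observed_edges = x$observed_edges,
    null_mean = x$null_mean,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    n_nodes = x$n_nodes,
    null_scheme = x$null_scheme
  )
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!file.rename(tmp, path)) {
    stop_mitonet(sprintf("could not move temporary file into place at '%s'.", path))
  }
  invisible(path)
}
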