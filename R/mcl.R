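#' Markov clustering (MCL) of a weighted network
#'
#' From-scratch implementation of the Markov Cluster algorithm. The
#' weighted adjacency matrix is stabilised with self-loops, column
#' normalized into a column-stochastic matrix, and the expansion
#' (matrix power) / inflation (entrywise power followed by column
#' renormalization) pair is iterated, pruning entries below
#' `pruning_threshold`, until the matrix change falls below `tol` or
#' `max_iter` is reached. Clusters are read off the limit matrix: rows with
#' non-negligible diagonal mass are attractors, attractors connected
#' through non-zero entries form cluster cores, and every node joins the
#' cluster of the cores whose rows overlap its column. Nodes attracted to
#' several clusters are assigned to the largest one (ties broken by the
#' smallest cluster id). Disconnected components never merge; isolated
#' nodes become singleton clusters. The procedure is fully deterministic.
#'
#' @param graph Undirected [igraph][igraph::igraph-package]; an optional
#'   `weight` edge attribute is used as connection strength.
#' @param inflation Inflation exponent r > 1 (default 1.4); larger values
#'   give finer clusters.
#' @param expansion Expansion power e >= 2, integer (default 2).
#' @param pruning_threshold Entries below this are zeroed after each
#'   inflation (the per-column maximum is always kept); default 1e-5.
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on the max entrywise change
#'   (default 1e-8).
#' @param self_loops Self-loop policy: `"max"` (per-column maximum incident
#'   edge weight, the standard stabilisation; isolated nodes get 1),
#'   `"one"` (unit loops) or `"none"`.
#' @return An object of class `mcl_partition`: list with `membership`
#'   (tibble `node`, `cluster`; cluster ids are dense integers ordered by
#'   decreasing cluster size), `n_clusters`, `converged`, `iterations` and
#'   `params`. Non-convergence at `max_iter` produces a warning and
#'   `converged = FALSE`, never a silent result.
#' @examples
#' g <- igraph::make_graph(~ A - B - C - A, D - E - F - D)
#' mcl(g)$membership
#' @export
mcl <- function(graph,
                inflation = 1.4,
                expansion = 2,
                pruning_threshold = 1e-5,
                max_iter = 200,
                tol = 1e-8,
                self_loops = c("max", "one", "none")) {
  if (!igraph::is_igraph(graph) || igraph::vcount(graph) == 0L) {
    stop_mitonet("`graph` must be a non-empty igraph object.")
  }
  check_scalar_number(inflation, "inflation", min = 1, strict_min = TRUE)
  expansion <- check_count(expansion, "expansion", min = 2L)
  check_scalar_number(pruning_threshold, "pruning_threshold", min = 0, strict_min = TRUE)
  max_iter <- check_count(max_iter, "max_iter", min = 1L)
  check_scalar_number(tol, "tol", min = 0, strict_min = TRUE)
  self_loops <- match.arg(self_loops)

  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  A <- igraph::as_adjacency_matrix(
    graph, attr = if (!is.null(igraph::E(graph)$weight)) "weight" else NULL,
    sparse = FALSE
  )
  diag(A) <- 0
  n <- nrow(A)
  loop <- switch(self_loops,
    max = {
      m <- apply(A, 2L, max)
      ifelse(m > 0, m, 1)
    },
    one = rep(1, n),
    none = rep(0, n)
  )
  diag(A) <- loop
  # isolated nodes with no self-loop would give a zero column
  zero_col <- colSums(A) == 0
  if (any(zero_col)) diag(A)[zero_col] <- 1
  M <- sweep(A, 2L, colSums(A), "/")

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mx <- M
    for (k in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    # prune small entries, but never empty a column
    col_max <- apply(Mx, 2L, max)
    Mx[Mx < pruning_threshold & Mx < rep(col_max, each = n)] <- 0
    Mx <- sweep(Mx, 2L, colSums(Mx), "/")
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn(sprintf("MCL did not converge within %d iterations.", max_iter))
  }
  membership <- interpret_mcl_limit(M, attractor_tol = 1e-6)
  out <- structure(
    list(
      membership = tibble(node = nodes, cluster = membership),
      n_clusters = max(membership),
      converged = converged,
      iterations = iter,
      params = list(
        inflation = inflation, expansion = expansion,
        pruning_threshold = pruning_threshold, max_iter = max_iter,
        tol = tol, self_loops = self_loops
      )
    ),
    class = "mcl_partition"
  )
  out
}

# Read a partition from an MCL limit matrix. Shared cluster-extraction
# logic: attractors -> cores -> overlap resolution (largest cluster, then
# smallest id) -> dense size-ordered ids.
interpret_mcl_limit <- function(M, attractor_tol = 1e-6) {
  n <- nrow(M)
  attractors <- which(diag(M) > attractor_tol)
  if (length(attractors) == 0L) attractors <- seq_len(n) # degenerate fallback
  # cores: connected components among attractors through non-zero entries
  sub <- (M[attractors, attractors, drop = FALSE] > attractor_tol) |
    t(M[attractors, attractors, drop = FALSE] > attractor_tol)
  core_id <- components_boolean(sub)
  n_cores <- max(core_id)
  # candidate membership: node j belongs to core c if any attractor row of
  # the core has mass on column j
  member_mat <- matrix(FALSE, n_cores, n)
  for (c in seq_len(n_cores)) {
    rows <- attractors[core_id == c]
    member_mat[c, ] <- colSums(M[rows, , drop = FALSE] > attractor_tol) > 0
  }
  sizes <- rowSums(member_mat)
  assign <- integer(n)
  for (j in seq_len(n)) {
    cand <- which(member_mat[, j])
    if (length(cand) == 0L) {
      # no attractor mass (numerically); attach to the heaviest row
      cand <- core_id[which.max(M[attractors, j])]
    }
    if (length(cand) > 1L) {
      cand <- cand[order(-sizes[cand], cand)][1]
    }
    assign[j] <- cand
  }
  relabel_by_size(assign)
}

# connected components of a boolean adjacency matrix (tiny n)
components_boolean <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2L, any))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# dense integer labels ordered by decreasing cluster size; ties broken by
# first appearance so relabeling is deterministic
relabel_by_size <- function(assign) {
  tab <- table(assign)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  new_id <- integer(length(tab))
  new_id[ord] <- seq_along(ord)
  unname(new_id[match(assign, as.integer(names(tab)))])
}

#' @export
print.mcl_partition <- function(x, ...) {
  cat(sprintf(
    "MCL partition: %d nodes in %d clusters (inflation %.2f, %s in %d iterations)\n",
    nrow(x$membership), x$n_clusters, x$params$inflation,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  sizes <- sort(table(x$membership$cluster), decreasing = TRUE)
  cat("cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an MCL partition into a node-cluster tibble
#'
#' @param x An `mcl_partition`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `cluster`.
#' @export
tidy.mcl_partition <- function(x, ...) {
  x$membership
}

#' One-row summary of an MCL partition
#'
#' @param x An `mcl_partition`.
#' @param ... Unused.
#' @return Tibble with `n_nodes`, `n_clusters`, `largest_cluster`,
#'   `converged`, `iterations`, `inflation`.
#' @export
glance.mcl_partition <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$membership),
    n_clusters = x$n_clusters,
    largest_cluster = max(table(x$membership$cluster)),
    converged = x$converged,
    iterations = x$iterations,
    inflation = x$params$inflation
  )
}

#' Weighted Newman modularity of a partition
#'
#' @param graph Undirected igraph (optionally edge-weighted).
#' @param partition An `mcl_partition`, or a tibble with columns `node`
#'   and `cluster` covering every node of `graph`.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
network_modularity <- function(graph, partition) {
  if (inherits(partition, "mcl_partition")) partition <- partition$membership
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  idx <- match(nodes, partition$node)
  if (anyNA(idx)) {
    stop_mitonet(sprintf("partition does not cover node '%s'.",
                         nodes[which(is.na(idx))[1]]))
  }
  igraph::modularity(graph, membership = partition$cluster[idx],
                     weights = igraph::E(graph)$weight)
}

#' Write a cluster partition as TSV
#'
#' @param partition An `mcl_partition` or a `node`/`cluster` tibble.
#' @param path Output path.
#' @param header Extra metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, header = character()) {
  if (inherits(partition, "mcl_partition")) partition <- partition$membership
  write_tsv_atomic(partition[c("node", "cluster")], path, header = header)
}
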