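# Independent oracles used across the suite. Each is written from the
# algorithm definition with different machinery from the package code, so
# agreement is evidence, not tautology.

# Dense-matrix Markov-clustering reference: no pruning, convergence at
# 1e-12, loop-based cluster extraction following the documented rule
# (attractor cores; overlaps to the largest cluster, ties to the smallest
# id; labels dense and size-ordered).
mcl_reference <- function(graph, inflation, expansion = 2, max_iter = 10000) {
  n <- igraph::vcount(graph)
  w <- igraph::E(graph)$weight
  A <- igraph::as_adjacency_matrix(graph, attr = if (!is.null(w)) "weight" else NULL,
                                   sparse = FALSE)
  diag(A) <- 0
  for (j in seq_len(n)) {
    m <- max(A[, j])
    A[j, j] <- if (m > 0) m else 1
  }
  M <- apply(A, 2L, function(col) col / sum(col))
  if (n == 1L) M <- matrix(1, 1, 1)
  it <- 0L
  repeat {
    it <- it + 1L
    E <- M
    for (k in seq_len(expansion - 1L)) E <- E %*% M
    E <- E^inflation
    E <- apply(E, 2L, function(col) col / sum(col))
    if (max(abs(E - M)) < 1e-12 || it >= max_iter) {
      M <- E
      break
    }
    M <- E
  }
  thr <- 1e-6
  attractors <- which(diag(M) > thr)
  if (!length(attractors)) attractors <- seq_len(n)
  core <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (a in seq_along(attractors)) {
      for (b in seq_along(attractors)) {
        if (core[a] != core[b] &&
            (M[attractors[a], attractors[b]] > thr ||
             M[attractors[b], attractors[a]] > thr)) {
          core[core == core[b]] <- core[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cores <- unique(core)
  members <- lapply(cores, function(cid) {
    rows <- attractors[core == cid]
    which(colSums(M[rows, , drop = FALSE] > thr) > 0)
  })
  sizes <- lengths(members)
  assign <- integer(n)
  for (j in seq_len(n)) {
    cand <- which(vapply(members, function(m) j %in% m, TRUE))
    if (!length(cand)) {
      cand <- which.max(vapply(cores, function(cid) {
        rows <- attractors[core == cid]
        max(M[rows, j])
      }, 0))
    }
    if (length(cand) > 1L) cand <- cand[order(-sizes[cand], cand)][1]
    assign[j] <- cand
  }
  tab <- table(assign)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  new_id <- integer(length(tab))
  new_id[ord] <- seq_along(ord)
  unname(new_id[match(assign, as.integer(names(tab)))])
}

# random connected graph on 3..7 nodes, half of them edge-weighted
random_connected_graph <- function(seed) {
  set.seed(seed)
  n <- sample(3:7, 1)
  repeat {
    g <- igraph::sample_gnp(n, stats::runif(1, 0.3, 0.9))
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- paste0("n", seq_len(n))
  if (stats::runif(1) < 0.5) {
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.2, 1)
  }
  g
}

# exhaustive hypergeometric upper tail from binomial coefficients only
hyper_tail_enum <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up computed by hand from the definition
bh_by_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  if (m >= 2) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# partitions equal up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# tidy effect table (spot_id, contrast, effect_size) from a truth table of
# per-group planted effects
truth_to_contrasts <- function(truth, contrasts) {
  purrr::map_dfr(contrasts, function(ctr) {
    wide <- tidyr::pivot_wider(truth, id_cols = "spot_id",
                               names_from = "group", values_from = "effect")
    tibble::tibble(
      spot_id = wide$spot_id,
      contrast = paste(ctr[1], "vs", ctr[2]),
      effect_size = wide[[ctr[1]]] - wide[[ctr[2]]]
    )
  })
}
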