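#' Simulation configuration for a 2D-gel spot-intensity experiment
#'
#' Describes a synthetic gel experiment: a set of measured spots, an
#' albumin-like reference spot, experimental groups with a fixed number of
#' gels each, planted group effects on the log2 scale, a per-gel
#' multiplicative loading scale, and per-observation log-normal noise.
#'
#' The generative model for the intensity of spot \eqn{s} on gel \eqn{g}
#' belonging to group \eqn{G} is
#' \deqn{I_{sg} = 2^{\mu_s + \beta_{sG} + \gamma_g + \varepsilon_{sg}}}
#' with \eqn{\gamma_g \sim N(0, \sigma_{gel}^2)} shared by every spot on a
#' gel and \eqn{\varepsilon_{sg} \sim N(0, \sigma_{noise}^2)} independent per
#' observation. The reference spot has \eqn{\beta = 0} in every group, so
#' dividing by its intensity removes \eqn{\gamma_g} exactly.
#'
#' @param n_spots Number of measured spots (the reference spot is added on
#'   top of these).
#' @param n_gels_per_group Gels (biological replicates) per group; must be
#'   at least 2.
#' @param groups Ordered character vector of group labels.
#' @param planted_effects Tibble with columns `spot_id`, `group`, `effect`
#'   giving true additive log2 effects; spots/groups not listed have effect
#'   0. `NULL` means no effects anywhere.
#' @param gel_scale_sd SD of the per-gel log2 loading scale (>= 0).
#' @param noise_sd SD of per-observation log2 noise (>= 0).
#' @param reference_spot_id Identifier of the albumin-like reference spot.
#' @param seed Integer RNG seed.
#'
#' @return A list of class `spot_sim_config`.
#' @seealso [simulate_spot_table()]
#' @export
spot_sim_config <- function(n_spots = 300,
                            n_gels_per_group = 3,
                            groups = c("sham", "Isch", "I/R", "PostC"),
                            planted_effects = NULL,
                            gel_scale_sd = 1,
                            noise_sd = 0.25,
                            reference_spot_id = "ALB",
                            seed = 1L) {
  n_spots <- check_count(n_spots, "n_spots", min = 1L)
  n_gels_per_group <- check_count(n_gels_per_group, "n_gels_per_group", min = 2L)
  check_scalar_number(gel_scale_sd, "gel_scale_sd", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.character(groups) || length(groups) < 2L || anyDuplicated(groups)) {
    stop_mitonet("`groups` must be at least two distinct group labels.")
  }
  if (!is.character(reference_spot_id) || length(reference_spot_id) != 1L) {
    stop_mitonet("`reference_spot_id` must be a single string.")
  }
  spot_ids <- sprintf("S%03d", seq_len(n_spots))
  if (reference_spot_id %in% spot_ids) {
    stop_mitonet("`reference_spot_id` collides with a measured spot id.")
  }
  if (!is.null(planted_effects)) {
    planted_effects <- as_tibble(planted_effects)
    needed <- c("spot_id", "group", "effect")
    if (!all(needed %in% names(planted_effects))) {
      stop_mitonet("`planted_effects` needs columns spot_id, group, effect.")
    }
    bad_spot <- setdiff(planted_effects$spot_id, c(spot_ids, reference_spot_id))
    if (length(bad_spot)) {
      stop_mitonet(sprintf(
        "`planted_effects` names unknown spot(s): %s.",
        paste(utils::head(bad_spot, 3), collapse = ", ")
      ))
    }
    if (!all(planted_effects$group %in% groups)) {
      stop_mitonet("`planted_effects` names a group absent from `groups`.")
    }
    if (reference_spot_id %in% planted_effects$spot_id &&
        any(planted_effects$effect[planted_effects$spot_id == reference_spot_id] != 0)) {
      stop_mitonet("`planted_effects` must be 0 for `reference_spot_id`.")
    }
  }
  structure(
    list(
      n_spots = n_spots, n_gels_per_group = n_gels_per_group,
      groups = groups, planted_effects = planted_effects,
      gel_scale_sd = gel_scale_sd, noise_sd = noise_sd,
      reference_spot_id = reference_spot_id, seed = seed,
      spot_ids = spot_ids
    ),
    class = "spot_sim_config"
  )
}

#' Simulate a spot-intensity table with known ground truth
#'
#' Draws a gel experiment from the generative model described in
#' [spot_sim_config()]. The ground-truth effect table is always returned
#' alongside the data so downstream tests never have to re-derive it.
#'
#' @param config A [spot_sim_config()].
#' @return A list of class `spot_sim` with elements:
#'   \describe{
#'     \item{spots}{Long tibble: `spot_id`, `gel_id`, `group`, `intensity`.}
#'     \item{truth}{Tibble of true log2 effects: `spot_id`, `group`, `effect`
#'       (complete spot x group grid, reference spot included at 0).}
#'     \item{gel_groups}{Tibble `gel_id`, `group`.}
#'     \item{reference_spot_id}{The reference spot identifier.}
#'     \item{config}{The configuration used.}
#'   }
#' @examples
#' sim <- simulate_spot_table(spot_sim_config(n_spots = 10, seed = 42))
#' dplyr::count(sim$spots, group)
#' @export
simulate_spot_table <- function(config) {
  if (!inherits(config, "spot_sim_config")) {
    stop_mitonet("`config` must be created by spot_sim_config().")
  }
  spot_ids <- c(config$spot_ids, config$reference_spot_id)
  n_spot <- length(spot_ids)
  gel_groups <- tidyr::expand_grid(
    group = config$groups,
    rep = seq_len(config$n_gels_per_group)
  ) |>
    mutate(gel_id = sprintf("gel_%s_%d", gsub("[^A-Za-z0-9]", "", .data$group), .data$rep)) |>
    select("gel_id", "group")

  # complete effect grid, 0 unless planted; reference spot always 0
  truth <- tidyr::expand_grid(spot_id = spot_ids, group = config$groups)
  if (is.null(config$planted_effects)) {
    truth$effect <- 0
  } else {
    truth <- truth |>
      left_join(config$planted_effects, by = c("spot_id", "group")) |>
      mutate(effect = tidyr::replace_na(.data$effect, 0))
  }

  n_gel <- nrow(gel_groups)
  eff_mat <- matrix(truth$effect, nrow = n_spot, byrow = TRUE,
                    dimnames = list(spot_ids, config$groups))
  spots <- withr::with_seed(config$seed, {
    # stable baseline abundances; the reference spot is the most abundant,
    # as albumin is on a serum-contaminated gel
    mu <- stats::rnorm(n_spot, mean = 10, sd = 1)
    names(mu) <- spot_ids
    mu[config$reference_spot_id] <- 14
    gel_scale <- stats::rnorm(n_gel, 0, config$gel_scale_sd)
    eps <- matrix(stats::rnorm(n_spot * n_gel, 0, config$noise_sd), n_spot, n_gel)
    log2_int <- mu + eff_mat[, gel_groups$group, drop = FALSE] +
      rep(gel_scale, each = n_spot) + eps
    tibble(
      spot_id = rep(spot_ids, times = n_gel),
      gel_id = rep(gel_groups$gel_id, each = n_spot),
      group = rep(gel_groups$group, each = n_spot),
      intensity = 2^as.vector(log2_int)
    )
  })
  structure(
    list(
      spots = spots, truth = truth, gel_groups = gel_groups,
      reference_spot_id = config$reference_spot_id, config = config
    ),
    class = "spot_sim"
  )
}

#' Configuration for a planted-partition (stochastic block model) interactome
#'
#' @param cluster_sizes Integer vector of planted cluster sizes; singleton
#'   clusters are allowed and act as unstructured background.
#' @param p_within Edge probability inside a planted cluster.
#' @param p_between Edge probability across clusters; must satisfy
#'   `0 <= p_between < p_within <= 1`.
#' @param score_range Interval for simulated STRING-style combined scores on
#'   the 0-1000 scale.
#' @param node_ids Optional node identifiers (length `sum(cluster_sizes)`);
#'   defaults to `P001`, `P002`, ...
#' @param seed Integer RNG seed.
#' @return A list of class `network_sim_config`.
#' @export
network_sim_config <- function(cluster_sizes,
                               p_within = 0.5,
                               p_between = 0.02,
                               score_range = c(400, 999),
                               node_ids = NULL,
                               seed = 1L) {
  if (!is.numeric(cluster_sizes) || length(cluster_sizes) < 1L ||
      any(cluster_sizes < 1) || any(cluster_sizes != as.integer(cluster_sizes))) {
    stop_mitonet("`cluster_sizes` must be positive integers.")
  }
  cluster_sizes <- as.integer(cluster_sizes)
  check_scalar_number(p_within, "p_within", min = 0)
  check_scalar_number(p_between, "p_between", min = 0)
  if (p_within > 1 || p_between >= 1) {
    stop_mitonet("edge probabilities must lie in [0, 1].")
  }
  if (p_between > p_within) {
    stop_mitonet("`p_between` must not exceed `p_within`.")
  }
  n <- sum(cluster_sizes)
  if (is.null(node_ids)) {
    node_ids <- sprintf("P%03d", seq_len(n))
  }
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    stop_mitonet("`node_ids` must be `sum(cluster_sizes)` unique identifiers.")
  }
  if (length(score_range) != 2L || score_range[1] > score_range[2] ||
      score_range[1] < 0 || score_range[2] > 1000) {
    stop_mitonet("`score_range` must be an increasing interval within [0, 1000].")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(cluster_sizes = cluster_sizes, p_within = p_within,
         p_between = p_between, score_range = score_range,
         node_ids = node_ids, seed = seed),
    class = "network_sim_config"
  )
}

#' Simulate a planted-partition interactome
#'
#' Draws an undirected stochastic block model: node pairs inside the same
#' planted cluster are connected with probability `p_within`, pairs across
#' clusters with `p_between`. Edge confidences (combined scores) are drawn
#' uniformly from `score_range` and rescaled to \[0, 1\] weights.
#'
#' @param config A [network_sim_config()].
#' @return A list of class `interactome_sim` with elements `graph` (an
#'   undirected [igraph][igraph::igraph-package] with a `weight` edge
#'   attribute in \[0, 1\]) and `membership` (tibble `node`, `cluster` of the
#'   planted labels).
#' @examples
#' sim <- simulate_interactome(network_sim_config(c(5, 5), p_within = 1,
#'                                                p_between = 0, seed = 7))
#' igraph::ecount(sim$graph)
#' @export
simulate_interactome <- function(config) {
  if (!inherits(config, "network_sim_config")) {
    stop_mitonet("`config` must be created by network_sim_config().")
  }
  n <- sum(config$cluster_sizes)
  labels <- rep(seq_along(config$cluster_sizes), times = config$cluster_sizes)
  # all unordered pairs; fine at the scales simulated here
  pairs <- utils::combn(n, 2L)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  p <- ifelse(same, config$p_within, config$p_between)
  edges <- withr::with_seed(config$seed, {
    keep <- stats::runif(length(p)) < p
    scores <- round(stats::runif(sum(keep), config$score_range[1], config$score_range[2]))
    list(keep = keep, scores = scores)
  })
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- config$node_ids
  if (any(edges$keep)) {
    ends <- pairs[, edges$keep, drop = FALSE]
    g <- igraph::add_edges(g, as.vector(ends))
    igraph::E(g)$weight <- edges$scores / 1000
  }
  structure(
    list(
      graph = g,
      membership = tibble(node = config$node_ids, cluster = labels),
      config = config
    ),
    class = "interactome_sim"
  )
}

#' Simulate annotation gene sets matched to planted clusters
#'
#' Emits one term per planted cluster containing exactly its members, plus
#' decoy terms of randomly drawn members, as a GMT-writable collection.
#'
#' @param true_clusters Named list of character vectors, one per planted
#'   cluster (names become term ids; unnamed lists get `CLUST1`, ...).
#' @param universe Character vector of all annotatable identifiers; decoy
#'   members are drawn from it. Defaults to the union of cluster members.
#' @param n_decoy_terms Number of random decoy terms.
#' @param decoy_size Size range (inclusive) for decoy terms; capped at the
#'   universe size.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `term_id`, `description`, `members`
#'   (list-column), usable with [write_gmt()] and [enrich_sets()].
#' @export
simulate_annotations <- function(true_clusters,
                                 universe = NULL,
                                 n_decoy_terms = 0,
                                 decoy_size = c(5, 25),
                                 seed = 1L) {
  if (!is.list(true_clusters) || length(true_clusters) == 0L ||
      any(lengths(true_clusters) == 0L)) {
    stop_mitonet("`true_clusters` must be a non-empty list of non-empty sets.")
  }
  n_decoy_terms <- check_count(n_decoy_terms, "n_decoy_terms", min = 0L)
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(names(true_clusters))) {
    names(true_clusters) <- sprintf("CLUST%d", seq_along(true_clusters))
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(true_clusters)))
  }
  real <- tibble(
    term_id = names(true_clusters),
    description = sprintf("planted cluster %s", names(true_clusters)),
    members = unname(lapply(true_clusters, as.character))
  )
  if (n_decoy_terms == 0L) {
    return(real)
  }
  decoys <- withr::with_seed(seed, {
    sizes <- sample(seq(min(decoy_size[1], length(universe)),
                        min(decoy_size[2], length(universe))),
                    n_decoy_terms, replace = TRUE)
    lapply(sizes, function(k) sample(universe, k))
  })
  bind_rows(real, tibble(
    term_id = sprintf("DECOY%03d", seq_len(n_decoy_terms)),
    description = "random decoy term",
    members = decoys
  ))
}

#' Simulate a TF-to-target regulatory linkset with planted opposite regulation
#'
#' Builds a directed regulator-to-target linkset over the nodes of an
#' interactome. A configurable number of transcription factors are planted
#' as "opposite-regulation" TFs: every one of their in-network targets has
#' true log fold changes of opposite sign, both exceeding the magnitude
#' threshold, in the revascularization-vs-ischemia and
#' post-conditioning-vs-ischemia contrasts. All remaining TFs target only
#' nodes that fail that predicate, so the planted set is exactly the ground
#' truth for the downstream screen.
#'
#' @param network_nodes Character vector of node identifiers available as
#'   targets.
#' @param effects Tibble of true log2 effects per group (`spot_id`, `group`,
#'   `effect`), as returned in `simulate_spot_table()$truth`.
#' @param n_tfs Total number of TFs.
#' @param targets_per_tf Targets drawn per TF (capped at the eligible pool).
#' @param n_opposite_tfs Number of planted opposite-regulation TFs
#'   (`<= n_tfs`).
#' @param group_ref,group_a,group_b Group labels defining the two screened
#'   contrasts `group_a` vs `group_ref` and `group_b` vs `group_ref`.
#' @param threshold Magnitude threshold of the opposite-regulation
#'   predicate (log2 units).
#' @param seed Integer RNG seed.
#' @return A list of class `linkset_sim` with elements `linkset` (tibble
#'   `tf`, `target`, `source`) and `opposite_tfs` (character vector of
#'   planted opposite-regulation TF ids).
#' @export
simulate_linkset <- function(network_nodes,
                             effects,
                             n_tfs = 20,
                             targets_per_tf = 5,
                             n_opposite_tfs = 3,
                             group_ref = "Isch",
                             group_a = "I/R",
                             group_b = "PostC",
                             threshold = 0.5,
                             seed = 1L) {
  if (length(network_nodes) == 0L) {
    stop_mitonet("`network_nodes` must be non-empty.")
  }
  n_tfs <- check_count(n_tfs, "n_tfs", min = 1L)
  targets_per_tf <- check_count(targets_per_tf, "targets_per_tf", min = 1L)
  n_opposite_tfs <- check_count(n_opposite_tfs, "n_opposite_tfs", min = 0L)
  if (n_opposite_tfs > n_tfs) {
    stop_mitonet("`n_opposite_tfs` must not exceed `n_tfs`.")
  }
  seed <- check_count(seed, "seed", min = 0L)

  wide <- effects |>
    filter(.data$spot_id %in% network_nodes,
           .data$group %in% c(group_ref, group_a, group_b)) |>
    tidyr::pivot_wider(id_cols = "spot_id", names_from = "group",
                       values_from = "effect")
  for (g in c(group_ref, group_a, group_b)) {
    if (!g %in% names(wide)) wide[[g]] <- 0
  }
  lfc_a <- wide[[group_a]] - wide[[group_ref]]
  lfc_b <- wide[[group_b]] - wide[[group_ref]]
  opp <- sign(lfc_a) != sign(lfc_b) & abs(lfc_a) > threshold & abs(lfc_b) > threshold
  pool_opp <- wide$spot_id[opp]
  pool_bg <- wide$spot_id[!opp]
  if (n_opposite_tfs > 0L && length(pool_opp) == 0L) {
    stop_mitonet(paste0(
      "cannot plant opposite-regulation TFs: no network node has opposite ",
      "true effects above the threshold in both contrasts."
    ))
  }
  if (n_opposite_tfs < n_tfs && length(pool_bg) == 0L) {
    stop_mitonet("cannot plant background TFs: every network node is opposite-regulated.")
  }
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  opposite_tfs <- tf_ids[seq_len(n_opposite_tfs)]
  linkset <- withr::with_seed(seed, {
    purrr::map2_dfr(tf_ids, tf_ids %in% opposite_tfs, function(tf, is_opp) {
      pool <- if (is_opp) pool_opp else pool_bg
      k <- min(targets_per_tf, length(pool))
      tibble(tf = tf, target = sample(pool, k), source = "sim")
    })
  })
  structure(
    list(linkset = linkset, opposite_tfs = opposite_tfs),
    class = "linkset_sim"
  )
}

#' Planted effects of the default synthetic study
#'
#' The default scenario mirrors the scale of a 2D-gel mitochondrial
#' proteomics study of cardiac ischemia: 26 of 300 spots carry a true
#' absolute log2 fold change of 1, organised in three functional modules.
#' One module responds only to post-conditioning; one is down-regulated by
#' direct revascularization but up-regulated by post-conditioning (and is
#' therefore opposite-regulated in the two contrasts against ischemia); one
#' mixes up- and down-regulation under post-conditioning.
#'
#' @param effect_size Absolute planted log2 effect (default 1).
#' @return A list with `effects` (tibble `spot_id`, `group`, `effect`) and
#'   `modules` (named list of spot-id vectors, one per module).
#' @export
default_planted_effects <- function(effect_size = 1) {
  check_scalar_number(effect_size, "effect_size", min = 0, strict_min = TRUE)
  modules <- list(
    TCA = sprintf("S%03d", 1:10),
    OXPHOS = sprintf("S%03d", 11:18),
    NONMET = sprintf("S%03d", 19:26)
  )
  effects <- bind_rows(
    tibble(spot_id = modules$TCA, group = "PostC", effect = effect_size),
    tibble(spot_id = modules$OXPHOS, group = "I/R", effect = -effect_size),
    tibble(spot_id = modules$OXPHOS, group = "PostC", effect = effect_size),
    tibble(spot_id = modules$NONMET, group = "PostC",
           effect = effect_size * rep(c(1, -1), length.out = 8))
  )
  list(effects = effects, modules = modules)
}
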