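#' Pipeline configuration
#'
#' Assembles and validates every tunable of the end-to-end synthetic
#' analysis in one flat list. Unknown arguments are an error (fail-fast),
#' so a typo cannot silently fall back to a default.
#'
#' @param n_spots Measured spots in the synthetic study (default 300).
#' @param n_gels_per_group Gels per experimental group (default 3).
#' @param groups Group labels (default sham, Isch, I/R, PostC).
#' @param effect_size Absolute planted log2 effect (default 1).
#' @param gel_scale_sd,noise_sd Generator SDs, log2 units (defaults 1 and
#'   0.25).
#' @param threshold Differential/opposite-regulation threshold on the
#'   absolute effect size (default 0.5, strict).
#' @param log_base Logarithm base for fold changes (default 2).
#' @param n_boot Bootstrap replicates per spot and contrast (default 1000).
#' @param score_cutoff STRING-style confidence cutoff in \[0, 1\]
#'   (default 0.4).
#' @param inflation MCL inflation parameter (default 1.4).
#' @param n_permutations Permutations of the PPI-enrichment test
#'   (default 1000).
#' @param p_within,p_between Planted-partition edge probabilities
#'   (defaults 0.5 and 0.02).
#' @param n_decoy_terms Decoy annotation terms (default 20).
#' @param n_tfs,targets_per_tf,n_opposite_tfs Regulatory linkset layout
#'   (defaults 20, 5, 3).
#' @param contrasts List of group pairs `c(numerator, denominator)`;
#'   defaults to the six pairwise contrasts of the four-group design.
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_spots = 300,
                            n_gels_per_group = 3,
                            groups = c("sham", "Isch", "I/R", "PostC"),
                            effect_size = 1,
                            gel_scale_sd = 1,
                            noise_sd = 0.25,
                            threshold = 0.5,
                            log_base = 2,
                            n_boot = 1000,
                            score_cutoff = 0.4,
                            inflation = 1.4,
                            n_permutations = 1000,
                            p_within = 0.5,
                            p_between = 0.02,
                            n_decoy_terms = 20,
                            n_tfs = 20,
                            targets_per_tf = 5,
                            n_opposite_tfs = 3,
                            contrasts = NULL,
                            seed = 1L) {
  if (is.null(contrasts)) {
    contrasts <- list(
      c("Isch", "sham"), c("I/R", "sham"), c("PostC", "sham"),
      c("I/R", "Isch"), c("PostC", "Isch"), c("PostC", "I/R")
    )
  }
  cfg <- list(
    n_spots = check_count(n_spots, "n_spots", min = 26L),
    n_gels_per_group = check_count(n_gels_per_group, "n_gels_per_group", min = 2L),
    groups = groups,
    effect_size = effect_size,
    gel_scale_sd = gel_scale_sd,
    noise_sd = noise_sd,
    threshold = check_scalar_number(threshold, "threshold", min = 0, strict_min = TRUE),
    log_base = log_base,
    n_boot = check_count(n_boot, "n_boot", min = 1L),
    score_cutoff = score_cutoff,
    inflation = inflation,
    n_permutations = check_count(n_permutations, "n_permutations", min = 100L),
    p_within = p_within,
    p_between = p_between,
    n_decoy_terms = n_decoy_terms,
    n_tfs = n_tfs,
    targets_per_tf = targets_per_tf,
    n_opposite_tfs = n_opposite_tfs,
    contrasts = contrasts,
    seed = check_count(seed, "seed", min = 0L)
  )
  bad <- vapply(contrasts, function(x) length(x) != 2L || !all(x %in% groups), TRUE)
  if (any(bad)) {
    stop_mitonet("every contrast must be a pair of known group labels.")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic analysis end to end
#'
#' Orchestrates every stage on a simulated study with known ground truth:
#' simulate spot table, interactome, annotations and regulatory linkset;
#' normalize by the reference spot; bootstrap effect sizes for all
#' contrasts; call differential spots; induce the differential PPI network
#' and test its edge enrichment; cluster it with MCL; run
#' overrepresentation analysis per cluster; extend with the regulatory
#' linkset and screen for opposite-regulation TFs. All artifacts are
#' written atomically under `out_dir`, each with a commented metadata
#' header (tool version, configuration hash, master seed) and no
#' timestamps, so two runs with the same seed are byte-identical.
#'
#' If no spot passes the differential threshold the pipeline stops cleanly
#' after the differential stage with an explanatory message.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `mitonet_pipeline` with the in-memory
#'   results of every stage (`sim`, `results`, `differential`, `network`,
#'   `enrichment_test`, `partition`, `enrichment`, `extended`, `screen`,
#'   ground truth, and `files`, the named vector of written paths).
#' @examples
#' \donttest{
#' res <- run_pipeline(tempfile("mitonet"),
#'                     pipeline_config(n_spots = 40, n_boot = 50,
#'                                     n_permutations = 100, seed = 7))
#' res$screen
#' }
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_mitonet("`config` must be created by pipeline_config().")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- fnv1a_hash(deparse(unclass(config)))
  hdr <- metadata_header(seed = config$seed, config_hash = hash)
  seeds <- spawn_seeds(config$seed, 6L)
  files <- c()
  path <- function(name) file.path(out_dir, name)

  # --- stage 1: simulate -------------------------------------------------
  planted <- default_planted_effects(config$effect_size)
  sim <- simulate_spot_table(spot_sim_config(
    n_spots = config$n_spots,
    n_gels_per_group = config$n_gels_per_group,
    groups = config$groups,
    planted_effects = planted$effects,
    gel_scale_sd = config$gel_scale_sd,
    noise_sd = config$noise_sd,
    seed = seeds[1]
  ))
  module_sizes <- lengths(planted$modules)
  net_sim <- simulate_interactome(network_sim_config(
    cluster_sizes = c(module_sizes, rep(1L, config$n_spots - sum(module_sizes))),
    p_within = config$p_within,
    p_between = config$p_between,
    node_ids = sim$config$spot_ids,
    seed = seeds[2]
  ))
  annotations <- simulate_annotations(
    planted$modules,
    universe = sim$config$spot_ids,
    n_decoy_terms = config$n_decoy_terms,
    seed = seeds[3]
  )
  link_sim <- simulate_linkset(
    network_nodes = sim$config$spot_ids,
    effects = sim$truth,
    n_tfs = config$n_tfs,
    targets_per_tf = config$targets_per_tf,
    n_opposite_tfs = config$n_opposite_tfs,
    # ground-truth predicate on the true planted effects: any cut below the
    # planted magnitude selects the same pool, independent of the analysis
    # threshold
    threshold = config$effect_size / 2,
    seed = seeds[4]
  )
  write_spot_table(sim$spots, path("spot_table.csv"), path("gel_groups.tsv"),
                   header = hdr)
  write_string_tsv(net_sim$graph, path("interactome.tsv"), header = hdr)
  write_gmt(annotations, path("annotations.gmt"), header = hdr)
  write_linkset(link_sim$linkset, path("linkset.tsv"), header = hdr)
  write_tsv_atomic(sim$truth, path("truth_effects.tsv"), header = hdr)
  write_tsv_atomic(net_sim$membership, path("truth_clusters.tsv"), header = hdr)
  write_tsv_atomic(tibble(tf = link_sim$opposite_tfs),
                   path("truth_opposite_tfs.tsv"), header = hdr)
  files <- c(files,
             spot_table = path("spot_table.csv"),
             gel_groups = path("gel_groups.tsv"),
             interactome = path("interactome.tsv"),
             annotations = path("annotations.gmt"),
             linkset = path("linkset.tsv"),
             truth_effects = path("truth_effects.tsv"),
             truth_clusters = path("truth_clusters.tsv"),
             truth_opposite_tfs = path("truth_opposite_tfs.tsv"))

  # --- stage 2: normalization + bootstrap differential expression --------
  norm <- normalize_spots(sim$spots, sim$reference_spot_id)
  results <- bootstrap_effects(
    norm,
    contrasts = config$contrasts,
    spots = sim$config$spot_ids,
    n_boot = config$n_boot,
    seed = seeds[5],
    threshold = config$threshold,
    log_base = config$log_base
  )
  write_diffexp(results, path("differential.tsv"), header = hdr)
  files <- c(files, differential = path("differential.tsv"))
  differential <- call_differential(results, threshold = config$threshold,
                                    reference_spot_id = sim$reference_spot_id)
  diff_set <- sort(unique(differential$spot_id))
  out <- list(
    config = config, sim = sim, annotations = annotations,
    interactome = net_sim, linkset = link_sim,
    results = results, differential = differential, diff_set = diff_set,
    files = files
  )
  class(out) <- "mitonet_pipeline"
  if (length(diff_set) == 0L) {
    rlang::inform(sprintf(
      "no spot exceeds |effect size| > %g; stopping after the differential stage.",
      config$threshold
    ))
    return(invisible(out))
  }

  # --- stage 3: differential PPI network + enrichment test ---------------
  network <- induce_network(net_sim$graph, diff_set)
  enrichment_test <- ppi_enrichment(net_sim$graph, diff_set,
                                    n_permutations = config$n_permutations,
                                    seed = seeds[6])
  write_enrichment_json(enrichment_test, path("ppi_enrichment.json"),
                        meta = list(seed = config$seed, config_hash = hash))

  # --- stage 4: MCL clustering ------------------------------------------
  partition <- mcl(network, inflation = config$inflation)
  write_partition(partition, path("clusters.tsv"), header = hdr)

  # --- stage 5: per-cluster overrepresentation --------------------------
  universe <- annotated_universe(net_sim$graph, annotations)
  enrichment <- purrr::map_dfr(
    sort(unique(partition$membership$cluster)),
    function(cl) {
      members <- partition$membership$node[partition$membership$cluster == cl]
      if (length(intersect(members, universe)) == 0L) return(NULL)
      res <- enrich_sets(members, annotations, universe)
      mutate(as_tibble(res), cluster = cl, .before = 1L)
    }
  )
  write_enrichment_tsv(enrichment, path("enrichment.tsv"), header = hdr)

  # --- stage 6: regulatory extension + opposite-regulation screen -------
  extended <- extend_regulatory(network, link_sim$linkset, node_effects = results)
  screen <- screen_opposite_tfs(extended, threshold = config$threshold)
  write_tf_screen(screen, path("tf_candidates.tsv"), header = hdr)
  write_graphml(as_annotated_graph(extended, partition), path("network.graphml"),
                header = hdr)
  files <- c(files,
             ppi_enrichment = path("ppi_enrichment.json"),
             clusters = path("clusters.tsv"),
             enrichment = path("enrichment.tsv"),
             tf_candidates = path("tf_candidates.tsv"),
             network = path("network.graphml"))

  out$network <- network
  out$enrichment_test <- enrichment_test
  out$partition <- partition
  out$enrichment <- enrichment
  out$extended <- extended
  out$screen <- screen
  out$files <- files
  invisible(out)
}

#' Default annotation universe
#'
#' All nodes of a background interactome that carry at least one
#' annotation.
#'
#' @param background Undirected igraph interactome.
#' @param annotations Annotation tibble with a `members` list-column.
#' @return Character vector of node identifiers.
#' @export
annotated_universe <- function(background, annotations) {
  intersect(igraph::V(background)$name, unique(unlist(annotations$members)))
}

#' @export
print.mitonet_pipeline <- function(x, ...) {
  cat(sprintf("mitonet pipeline run (seed %d)\n", x$config$seed))
  cat(sprintf("  differential spots: %d\n", length(x$diff_set)))
  if (!is.null(x$partition)) {
    cat(sprintf("  PPI enrichment p = %.4g; %d MCL clusters\n",
                x$enrichment_test$p_value, x$partition$n_clusters))
    cat(sprintf("  TFs in extended network: %d; opposite-regulation candidates: %d\n",
                length(x$extended$tfs), sum(x$screen$is_opposite_candidate)))
  }
  invisible(x)
}
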