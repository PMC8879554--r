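test_that("zero-noise, zero-effect tables are constant across gels", {
  cfg <- spot_sim_config(n_spots = 6, noise_sd = 0, gel_scale_sd = 0, seed = 3)
  sim <- simulate_spot_table(cfg)
  per_spot <- tapply(sim$spots$intensity, sim$spots$spot_id,
                     function(x) diff(range(x)))
  expect_true(all(per_spot == 0))
  expect_true(all(sim$spots$intensity > 0))
})

test_that("planted effects appear exactly in noise-free group medians", {
  eff <- tibble::tibble(spot_id = "S002", group = "PostC", effect = 1)
  cfg <- spot_sim_config(n_spots = 4, noise_sd = 0, gel_scale_sd = 0,
                         planted_effects = eff, seed = 5)
  sim <- simulate_spot_table(cfg)
  norm <- normalize_spots(sim$spots, sim$reference_spot_id)
  expect_equal(spot_logfc(norm, "S002", "PostC", "sham"), 1.0)
  expect_equal(spot_logfc(norm, "S001", "PostC", "sham"), 0.0)
})

test_that("reference-spot normalization cancels arbitrary gel scaling exactly", {
  eff <- tibble::tibble(spot_id = c("S001", "S003"), group = c("I/R", "PostC"),
                        effect = c(-0.8, 1.3))
  cfg <- spot_sim_config(n_spots = 5, noise_sd = 0, gel_scale_sd = 2,
                         planted_effects = eff, seed = 11)
  sim <- simulate_spot_table(cfg)
  norm <- normalize_spots(sim$spots, sim$reference_spot_id)
  # gel scale is huge, but the ratio to the reference removes it entirely
  expect_equal(spot_logfc(norm, "S001", "I/R", "sham"), -0.8)
  expect_equal(spot_logfc(norm, "S003", "PostC", "sham"), 1.3)
  # normalized values are identical across gels within a group
  spread <- norm |>
    dplyr::group_by(spot_id, group) |>
    dplyr::summarise(d = diff(range(value)), .groups = "drop")
  expect_true(all(spread$d < 1e-12))
})

test_that("spot simulation is deterministic under seed and validates config", {
  a <- simulate_spot_table(spot_sim_config(n_spots = 8, seed = 42))
  b <- simulate_spot_table(spot_sim_config(n_spots = 8, seed = 42))
  c <- simulate_spot_table(spot_sim_config(n_spots = 8, seed = 43))
  expect_identical(a$spots, b$spots)
  expect_false(identical(a$spots$intensity, c$spots$intensity))

  expect_error(spot_sim_config(n_gels_per_group = 1), "n_gels_per_group")
  expect_error(spot_sim_config(noise_sd = -1), "noise_sd")
  expect_error(spot_sim_config(planted_effects = tibble::tibble(
    spot_id = "S999", group = "sham", effect = 1
  ), n_spots = 5), "S999")
  expect_error(spot_sim_config(planted_effects = tibble::tibble(
    spot_id = "ALB", group = "sham", effect = 1
  )), "reference")
})

test_that("degenerate block-model probabilities give exact graphs", {
  tri2 <- simulate_interactome(network_sim_config(c(3, 3), p_within = 1,
                                                  p_between = 0, seed = 1))
  expect_equal(igraph::ecount(tri2$graph), 6)
  comp <- igraph::components(tri2$graph)
  expect_equal(comp$no, 2)
  expect_true(all(igraph::E(tri2$graph)$weight >= 0.4 &
                    igraph::E(tri2$graph)$weight <= 1))

  empty <- simulate_interactome(network_sim_config(c(3, 3), p_within = 0,
                                                   p_between = 0, seed = 1))
  expect_equal(igraph::ecount(empty$graph), 0)
})

test_that("within-cluster edge counts concentrate on the binomial expectation", {
  # 4 clusters of 10 at p_within = 0.5: E[within edges] = 4 * C(10,2) * 0.5 = 90
  counts <- vapply(1:200, function(s) {
    sim <- simulate_interactome(network_sim_config(rep(10, 4), p_within = 0.5,
                                                   p_between = 0, seed = s))
    igraph::ecount(sim$graph)
  }, 0)
  expect_lt(abs(mean(counts) - 90), 5)
})

test_that("interactome simulation is seed-deterministic and validates probabilities", {
  cfg <- network_sim_config(c(4, 4), p_within = 0.7, p_between = 0.1, seed = 9)
  g1 <- simulate_interactome(cfg)
  g2 <- simulate_interactome(cfg)
  expect_identical(igraph::as_edgelist(g1$graph), igraph::as_edgelist(g2$graph))
  expect_identical(igraph::E(g1$graph)$weight, igraph::E(g2$graph)$weight)
  expect_error(network_sim_config(c(3, 3), p_within = 0.1, p_between = 0.5),
               "p_between")
  expect_error(network_sim_config(c(3, 3), node_ids = c("a", "b")), "node_ids")
})

test_that("simulated annotations contain the planted clusters plus bounded decoys", {
  clusters <- list(A = c("x1", "x2", "x3"), B = c("y1", "y2"), C = c("z1"))
  ann0 <- simulate_annotations(clusters, n_decoy_terms = 0)
  expect_equal(nrow(ann0), 3)
  expect_identical(sort(ann0$members[[1]]), sort(clusters$A))

  uni <- c(unlist(clusters), paste0("u", 1:10))
  ann <- simulate_annotations(clusters, universe = uni, n_decoy_terms = 15,
                              decoy_size = c(2, 100), seed = 2)
  expect_equal(nrow(ann), 18)
  expect_false(anyDuplicated(ann$term_id) > 0)
  expect_true(all(lengths(ann$members) <= length(uni)))
  expect_true(all(unlist(ann$members[-(1:3)]) %in% uni))
})

test_that("a cluster queried against its own term reaches the minimum achievable p", {
  clusters <- list(A = paste0("a", 1:5))
  uni <- c(clusters$A, paste0("u", 1:15))
  ann <- simulate_annotations(clusters, universe = uni, n_decoy_terms = 0)
  res <- enrich_sets(clusters$A, ann, uni)
  # k = K = n = 5, N = 20: the single-point tail 1 / C(20,5)
  expect_equal(res$p_value[1], 1 / choose(20, 5))
})

test_that("planted opposite-regulation TFs are consistent with their definition", {
  sim <- simulate_spot_table(spot_sim_config(
    n_spots = 30, planted_effects = default_planted_effects(1)$effects |>
      dplyr::filter(spot_id %in% sprintf("S%03d", 1:30)),
    seed = 4
  ))
  ls <- simulate_linkset(sim$config$spot_ids, sim$truth, n_tfs = 6,
                         targets_per_tf = 3, n_opposite_tfs = 2, seed = 4)
  expect_length(ls$opposite_tfs, 2)
  truth_eff <- truth_to_contrasts(sim$truth,
                                  list(c("I/R", "Isch"), c("PostC", "Isch")))
  wide <- tidyr::pivot_wider(truth_eff, names_from = contrast,
                             values_from = effect_size)
  for (tf in unique(ls$linkset$tf)) {
    tg <- ls$linkset$target[ls$linkset$tf == tf]
    e <- wide[match(tg, wide$spot_id), ]
    opp <- sign(e$`I/R vs Isch`) != sign(e$`PostC vs Isch`) &
      abs(e$`I/R vs Isch`) > 0.5 & abs(e$`PostC vs Isch`) > 0.5
    if (tf %in% ls$opposite_tfs) expect_true(all(opp)) else expect_false(any(opp))
  }

  # zero planted TFs -> empty ground truth
  ls0 <- simulate_linkset(sim$config$spot_ids, sim$truth, n_tfs = 3,
                          targets_per_tf = 2, n_opposite_tfs = 0, seed = 1)
  expect_length(ls0$opposite_tfs, 0)

  # impossible to satisfy -> explicit error
  flat <- sim$truth |> dplyr::mutate(effect = 0)
  expect_error(
    simulate_linkset(sim$config$spot_ids, flat, n_tfs = 2, targets_per_tf = 2,
                     n_opposite_tfs = 1, seed = 1),
    "opposite"
  )
})
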