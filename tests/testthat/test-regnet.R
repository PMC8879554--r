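toy_effects <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      spot_id = r[[1]],
      contrast = c("I/R vs Isch", "PostC vs Isch"),
      effect_size = c(r[[2]], r[[3]])
    )
  })
}

test_that("extension keeps only in-network targets and leaves PPI edges alone", {
  g <- igraph::make_graph(~ A - B, B - C)
  ext <- extend_regulatory(g, tibble::tibble(tf = "TF1", target = "A"))
  expect_equal(ext$tfs, "TF1")
  expect_equal(nrow(ext$regulatory), 1)
  expect_equal(igraph::ecount(ext$ppi), 2)

  gone <- extend_regulatory(g, tibble::tibble(tf = "TF1", target = "X"))
  expect_length(gone$tfs, 0)
  expect_equal(nrow(gone$regulatory), 0)

  # extending twice with the same linkset changes nothing
  ls <- tibble::tibble(tf = c("TF1", "TF2"), target = c("A", "B"))
  once <- extend_regulatory(g, ls)
  twice <- extend_regulatory(once, ls)
  expect_equal(once$regulatory, twice$regulatory)
  expect_equal(once$tfs, twice$tfs)
})

test_that("every linked TF with an in-network target becomes one TF node", {
  sim <- simulate_interactome(network_sim_config(rep(4, 5), p_within = 0.9,
                                                 p_between = 0.1, seed = 6))
  nodes <- igraph::V(sim$graph)$name
  ls <- tibble::tibble(tf = sprintf("TF%02d", 1:20),
                       target = rep(nodes[1:10], 2))
  ext <- extend_regulatory(sim$graph, ls)
  expect_length(ext$tfs, 20)
  ag <- as_annotated_graph(ext)
  expect_equal(sum(igraph::V(ag)$kind == "tf"), 20)
  expect_equal(sum(igraph::E(ag)$kind == "regulatory"), 20)
  expect_equal(sum(igraph::E(ag)$kind == "ppi"), igraph::ecount(sim$graph))
})

test_that("the opposite-regulation predicate follows sign and strict magnitude", {
  g <- igraph::make_graph(~ A - B)
  ext <- extend_regulatory(g, tibble::tibble(tf = c("TF1", "TF2"),
                                             target = c("A", "B")))
  eff <- toy_effects(list("A", -0.6, 0.7), list("B", -0.6, -0.7))
  sc <- screen_opposite_tfs(ext, eff)
  expect_true(sc$is_opposite_candidate[sc$tf_id == "TF1"])
  expect_equal(sc$opposite_targets[sc$tf_id == "TF1"][[1]], "A")
  expect_false(sc$is_opposite_candidate[sc$tf_id == "TF2"]) # same sign

  # both magnitudes must strictly exceed the threshold
  eff2 <- toy_effects(list("A", -0.5, 0.7), list("B", 0, 0))
  sc2 <- screen_opposite_tfs(ext, eff2)
  expect_false(any(sc2$is_opposite_candidate))
})

test_that("targets without effects are skipped with a warning, not zeroed", {
  g <- igraph::make_graph(~ A - B)
  ext <- extend_regulatory(g, tibble::tibble(tf = "TF1", target = c("A", "B")))
  eff <- toy_effects(list("A", -0.6, 0.7))
  expect_warning(sc <- screen_opposite_tfs(ext, eff), "B")
  expect_equal(sc$opposite_targets[[1]], "A")
  expect_equal(sc$n_targets_in_network, 2)
})

test_that("raising the threshold never adds candidates", {
  sim <- simulate_interactome(network_sim_config(rep(3, 4), p_within = 1,
                                                 p_between = 0.2, seed = 12))
  nodes <- igraph::V(sim$graph)$name
  set.seed(3)
  eff <- purrr::map_dfr(nodes, function(nd) {
    tibble::tibble(spot_id = nd, contrast = c("I/R vs Isch", "PostC vs Isch"),
                   effect_size = stats::runif(2, -2, 2))
  })
  ls <- tibble::tibble(tf = rep(sprintf("TF%d", 1:4), each = 3),
                       target = sample(nodes, 12, replace = FALSE))
  ext <- extend_regulatory(sim$graph, ls)
  prev <- Inf
  for (thr in c(0.2, 0.5, 1, 2, 1e6)) {
    n <- sum(screen_opposite_tfs(ext, eff, threshold = thr)$is_opposite_candidate)
    expect_lte(n, prev)
    prev <- n
  }
  expect_equal(prev, 0) # effectively infinite threshold leaves none
})

test_that("the screen is invariant under consistent node relabeling", {
  g <- igraph::make_graph(~ A - B, B - C)
  ls <- tibble::tibble(tf = c("TF1", "TF2"), target = c("A", "C"))
  eff <- toy_effects(list("A", -0.8, 0.9), list("B", 1, 1), list("C", 0.6, -1.2))
  sc <- screen_opposite_tfs(extend_regulatory(g, ls), eff)

  ren <- c(A = "X", B = "Y", C = "Z")
  g2 <- g
  igraph::V(g2)$name <- unname(ren[igraph::V(g)$name])
  ls2 <- dplyr::mutate(ls, target = unname(ren[target]))
  eff2 <- dplyr::mutate(eff, spot_id = unname(ren[spot_id]))
  sc2 <- screen_opposite_tfs(extend_regulatory(g2, ls2), eff2)
  expect_equal(sc$tf_id, sc2$tf_id)
  expect_equal(sc$n_opposite_targets, sc2$n_opposite_targets)
  expect_equal(purrr::map(sc$opposite_targets, ~ unname(ren[.x])),
               sc2$opposite_targets)
})

test_that("planted opposite TFs are recovered exactly from true effects", {
  for (s in 1:3) {
    sim <- simulate_spot_table(spot_sim_config(
      n_spots = 40, planted_effects = default_planted_effects(1)$effects |>
        dplyr::filter(spot_id %in% sprintf("S%03d", 1:40)),
      seed = s
    ))
    net <- simulate_interactome(network_sim_config(
      c(10, 8, 8, rep(1, 14)), node_ids = sim$config$spot_ids, seed = s
    ))
    ls <- simulate_linkset(sim$config$spot_ids, sim$truth, n_tfs = 10,
                           targets_per_tf = 4, n_opposite_tfs = 3, seed = s)
    eff <- truth_to_contrasts(sim$truth,
                              list(c("I/R", "Isch"), c("PostC", "Isch")))
    ext <- extend_regulatory(net$graph, ls$linkset, node_effects = eff)
    sc <- screen_opposite_tfs(ext)
    expect_setequal(sc$tf_id[sc$is_opposite_candidate], ls$opposite_tfs)
  }
})
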