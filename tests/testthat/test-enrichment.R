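test_that("hypergeometric tail is exact on closed-form cases", {
  expect_equal(hypergeom_test(0, 5, 5, 20), 1) # P[X >= 0] = 1
  expect_equal(hypergeom_test(5, 5, 5, 20), 1 / 15504)
  expect_equal(hypergeom_test(5, 5, 5, 20), 1 / choose(20, 5))
  expect_error(hypergeom_test(6, 5, 5, 20), "bounds")
  expect_error(hypergeom_test(1, 21, 5, 20), "bounds")
  expect_error(hypergeom_test(1, 5, 21, 20), "bounds")
})

test_that("hypergeometric tail matches exhaustive enumeration (spot sample)", {
  set.seed(1)
  for (i in 1:200) {
    N <- sample(2:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_test(k, K, n, N), hyper_tail_enum(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:25) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_by_hand(p), tolerance = 1e-12)
    # order-preserving: permuting then unpermuting is the identity
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm])[order(perm)], bh_fdr(p))
    # monotone nondecreasing in sorted-p order, never above 1
    adj <- bh_fdr(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("overrepresentation ranks a planted cluster's own term first", {
  sim <- simulate_interactome(network_sim_config(c(8, 8, 8), p_within = 0.9,
                                                 p_between = 0.05, seed = 14))
  clusters <- split(sim$membership$node, sim$membership$cluster)
  names(clusters) <- paste0("MOD", names(clusters))
  ann <- simulate_annotations(clusters, universe = sim$membership$node,
                              n_decoy_terms = 10, decoy_size = c(3, 10),
                              seed = 2)
  res <- enrich_sets(clusters$MOD2, ann, sim$membership$node)
  expect_equal(res$term_id[1], "MOD2")
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})

test_that("degenerate and edge-case enrichment rows behave", {
  ann <- tibble::tibble(term_id = "ALL", description = "everything",
                        members = list(letters[1:5]))
  # everything annotated, everything queried: strength 0, p 1, fdr = p
  res <- enrich_sets(letters[1:5], ann, letters[1:5])
  expect_equal(res$strength, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$fdr, res$p_value) # single term: BH with m = 1

  # query members outside the universe are dropped and counted
  expect_message(
    res2 <- enrich_sets(c("a", "b", "zzz"), ann, letters[1:5]),
    "1 query member"
  )
  expect_equal(attr(res2, "n_dropped"), 1)
  expect_equal(res2$k, 2)

  expect_error(enrich_sets("zzz", ann, letters[1:5]), "universe")
  # terms with no universe members are skipped, not tested
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(term_id = "GHOST",
                                               description = "absent",
                                               members = list("qqq")))
  expect_equal(nrow(enrich_sets(letters[1:2], ann2, letters[1:5])), 1)
})

test_that("strength is the signed log10 observed/expected ratio", {
  ann <- tibble::tibble(
    term_id = c("T1", "T2"),
    description = "",
    members = list(letters[1:4], letters[5:10])
  )
  res <- enrich_sets(letters[1:5], ann, letters[1:20])
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$strength, log10((r1$k / r1$n) / (r1$K / r1$N)))
  expect_gt(r1$strength, 0) # enriched above expectation
  r2 <- res[res$term_id == "T2", ]
  expect_lt(r2$strength, 0) # depleted below expectation
})

test_that("null queries rarely reach fdr < 0.05", {
  sim <- simulate_interactome(network_sim_config(rep(1, 60), p_within = 0.1,
                                                 p_between = 0.1, seed = 4))
  ann <- simulate_annotations(list(A = igraph::V(sim$graph)$name[1:10]),
                              universe = igraph::V(sim$graph)$name,
                              n_decoy_terms = 19, decoy_size = c(5, 15),
                              seed = 5)
  set.seed(17)
  frac <- vapply(1:200, function(i) {
    q <- sample(igraph::V(sim$graph)$name, 12)
    res <- enrich_sets(q, ann, igraph::V(sim$graph)$name)
    mean(res$fdr < 0.05)
  }, 0)
  expect_lte(mean(frac), 0.05)
})
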