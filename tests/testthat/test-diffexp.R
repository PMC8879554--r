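toy_norm <- function(va, vb, spot = "S1", ga = "A", gb = "B") {
  na <- length(va)
  nb <- length(vb)
  tibble::tibble(
    spot_id = spot,
    gel_id = c(paste0("gA", seq_len(na)), paste0("gB", seq_len(nb))),
    group = c(rep(ga, na), rep(gb, nb)),
    value = c(va, vb)
  )
}

test_that("normalization divides by the reference and is scale-invariant", {
  spots <- tibble::tibble(
    spot_id = rep(c("S1", "ALB"), 2),
    gel_id = rep(c("g1", "g2"), each = 2),
    group = rep(c("A", "B"), each = 2),
    intensity = c(10, 100, 30, 50)
  )
  norm <- normalize_spots(spots, "ALB")
  expect_equal(norm$value[norm$spot_id == "S1"], c(0.1, 0.6))
  expect_true(all(norm$value[norm$spot_id == "ALB"] == 1))

  # multiplying one gel's raw values by 7 changes nothing
  scaled <- dplyr::mutate(spots, intensity = ifelse(gel_id == "g1",
                                                    intensity * 7, intensity))
  expect_equal(normalize_spots(scaled, "ALB"), norm)

  # idempotent on an already-normalized table
  expect_equal(normalize_spots(norm, "ALB"), norm)
})

test_that("normalization fails loudly on bad reference spots", {
  spots <- tibble::tibble(
    spot_id = rep(c("S1", "ALB"), 2),
    gel_id = rep(c("g1", "g2"), each = 2),
    group = "A",
    intensity = c(10, 0, 30, 50)
  )
  expect_error(normalize_spots(spots, "ALB"), "g1")
  expect_error(normalize_spots(spots, "NOPE"), "NOPE")
})

test_that("logFC is the log2 median ratio and exactly antisymmetric", {
  norm <- toy_norm(c(1, 2, 4), c(1, 1, 1))
  expect_equal(spot_logfc(norm, "S1", "A", "B"), 1.0) # log2(2/1)
  expect_equal(spot_logfc(norm, "S1", "B", "A"), -1.0)

  same <- toy_norm(c(2, 3, 5), c(2, 3, 5))
  expect_equal(spot_logfc(same, "S1", "A", "B"), 0)

  norm10 <- toy_norm(c(10, 10, 10), c(1, 1, 1))
  expect_equal(spot_logfc(norm10, "S1", "A", "B", log_base = 10), 1.0)

  zeros <- toy_norm(c(0, 0, 5), c(1, 1, 1))
  expect_error(spot_logfc(zeros, "S1", "A", "B"), "pseudocount")
})

test_that("bootstrap on constant groups gives a degenerate zero interval", {
  norm <- toy_norm(c(2, 2, 2), c(2, 2, 2))
  r <- bootstrap_effect(norm, "S1", "A", "B", n_boot = 100, seed = 1)
  expect_equal(r$effect_size, 0)
  expect_equal(c(r$ci_low, r$ci_high), c(0, 0))
  expect_false(r$is_differential)
  expect_equal(r$n_boot_used, 100)
})

test_that("the differential call is strict at the threshold", {
  # constant data where every replicate logFC is exactly the threshold
  norm <- toy_norm(rep(2, 3), rep(1, 3))
  r <- bootstrap_effect(norm, "S1", "A", "B", n_boot = 200, seed = 1,
                        threshold = 1)
  expect_identical(r$effect_size, 1)
  expect_false(r$is_differential) # "higher than" excludes equality
  r2 <- bootstrap_effect(norm, "S1", "A", "B", n_boot = 50, seed = 1,
                         threshold = 0.999)
  expect_true(r2$is_differential)
})

test_that("bootstrap is seed-deterministic and reports failed replicates", {
  norm <- toy_norm(c(0, 5, 6), c(1, 2, 3))
  r1 <- bootstrap_effect(norm, "S1", "A", "B", n_boot = 500, seed = 7)
  r2 <- bootstrap_effect(norm, "S1", "A", "B", n_boot = 500, seed = 7)
  expect_identical(r1, r2)
  # a resampled numerator median of 0 occurs with prob 7/27 per replicate
  expect_lt(r1$n_boot_used, 500)
  expect_gt(r1$n_boot_used, 250)
  expect_true(r1$ci_low <= r1$effect_size & r1$effect_size <= r1$ci_high)

  expect_error(bootstrap_effect(toy_norm(c(1, 2), c(3)), "S1", "A", "B"),
               ">= 2 gels")
})

test_that("effect size converges to the point logFC as noise vanishes", {
  for (sd in c(0.2, 0.05, 0)) {
    cfg <- spot_sim_config(
      n_spots = 2, noise_sd = sd, gel_scale_sd = 0.5,
      planted_effects = tibble::tibble(spot_id = "S001", group = "PostC",
                                       effect = 0.8),
      seed = 21
    )
    sim <- simulate_spot_table(cfg)
    norm <- normalize_spots(sim$spots, sim$reference_spot_id)
    r <- bootstrap_effect(norm, "S001", "PostC", "sham", n_boot = 400, seed = 5)
    expect_lt(abs(r$effect_size - r$logfc_point), 3 * sd + 1e-12)
    if (sd == 0) expect_equal(r$effect_size, 0.8)
  }
})

test_that("percentile intervals bound the planted effect most of the time at n=3", {
  # small-n bootstrap under-coverage is expected; the band checked is 80-100%
  hits <- vapply(1:60, function(i) {
    cfg <- spot_sim_config(
      n_spots = 2, noise_sd = 0.25, gel_scale_sd = 1,
      planted_effects = tibble::tibble(spot_id = "S001", group = "PostC",
                                       effect = 1),
      seed = 500 + i
    )
    sim <- simulate_spot_table(cfg)
    norm <- normalize_spots(sim$spots, sim$reference_spot_id)
    r <- bootstrap_effect(norm, "S001", "PostC", "sham", n_boot = 400, seed = i)
    r$ci_low <= 1 && 1 <= r$ci_high
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  expect_lte(mean(hits), 1.0)
})

test_that("bootstrap_effects tidies all spots and contrasts deterministically", {
  sim <- simulate_spot_table(spot_sim_config(n_spots = 4, seed = 2))
  norm <- normalize_spots(sim$spots, sim$reference_spot_id)
  contrasts <- list(c("Isch", "sham"), c("PostC", "Isch"))
  res <- bootstrap_effects(norm, contrasts, spots = sim$config$spot_ids,
                           n_boot = 100, seed = 3)
  expect_equal(nrow(res), 8)
  expect_setequal(unique(res$contrast), c("Isch vs sham", "PostC vs Isch"))
  res2 <- bootstrap_effects(norm, contrasts, spots = sim$config$spot_ids,
                            n_boot = 100, seed = 3)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("call_differential applies the strict threshold and drops the reference", {
  res <- tibble::tibble(
    spot_id = c("A", "B", "C", "ALB"),
    contrast = "PostC vs sham",
    effect_size = c(0.6, -0.7, 0.4, 2)
  )
  out <- call_differential(res, threshold = 0.5, reference_spot_id = "ALB")
  expect_setequal(out$spot_id, c("A", "B"))
  expect_equal(nrow(call_differential(res[0, ], 0.5)), 0)
  expect_error(call_differential(res, threshold = 0), "threshold")
})
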