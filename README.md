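# mitonet

Network-assisted differential analysis of mitochondrial proteomes measured
on 2D gels, in the tidyverse idiom.

## The problem

Comparative 2D-gel proteomics of the myocardium at risk — sham-operated
hearts versus ischemia (Isch), ischemia with direct revascularization
(I/R), and ischemia with post-conditioning (PostC) — produces small spot ×
gel intensity tables (typically three gels per group) with strong per-gel
loading differences. The question is not only which spots change, but how
the changed proteins hang together: do they form a connected module in the
protein–protein interaction (PPI) network, which functional pathways do its
clusters represent, and which transcription factors could drive targets
that respond in *opposite* directions under direct revascularization
versus post-conditioning?

`mitonet` implements that analysis chain as composable functions over
tibbles and igraph objects, plus seeded synthetic-data generators with
known ground truth so every stage is testable end to end without any
external database.

## The method

1. **Reference-spot normalization.** Spot intensities on each gel are
   divided by the albumin spot intensity of the same gel. Under the model
   `I_sg = 2^(mu_s + beta_sG + gamma_g + eps_sg)` (per-gel loading scale
   `gamma_g`, planted group effect `beta_sG`), this division removes
   `gamma_g` exactly.
2. **Bootstrap effect sizes.** The log fold change of spot *s* between
   groups A and B is `logFC = log2( median_A / median_B )` of the
   normalized values. Gels are resampled with replacement within each
   group, the logFC is recomputed per replicate, and the effect size is
   the median of the bootstrap distribution with a 95% percentile
   interval. A spot is differential when `|effect| > 0.5` (strict).
3. **PPI network and enrichment.** Differential proteins induce a
   subnetwork of a STRING-style weighted interactome; a permutation test
   compares its edge count against uniformly drawn node sets of the same
   size: `p = (1 + #{null >= observed}) / (n_perm + 1)`.
4. **Markov clustering (MCL).** A from-scratch MCL implementation
   (expansion `e = 2`, inflation `r = 1.4` by default, per-column-max
   self-loops, pruning `1e-5`) partitions the differential network into
   functional clusters.
5. **Overrepresentation analysis.** Each cluster is tested against
   annotation terms with the exact upper-tail hypergeometric test
   `P[X >= k]`, BH-FDR across terms, and STRING-style
   `strength = log10((k/n)/(K/N))`.
6. **Regulatory extension and opposite-regulation screen.** TF→target
   linkset edges whose target lies in the network add TF nodes; a TF is a
   candidate when at least one of its in-network targets satisfies
   `sign(logFC_{I/R vs Isch}) != sign(logFC_{PostC vs Isch})` with both
   magnitudes above the threshold.

## Worked example

```r
library(mitonet)

# a 4-group gel study: 60 spots + albumin, 3 gels/group, 26 planted effects
sim  <- simulate_spot_table(spot_sim_config(
  n_spots = 60, planted_effects = default_planted_effects()$effects, seed = 42))
norm <- normalize_spots(sim$spots, sim$reference_spot_id)
res  <- bootstrap_effects(norm, contrasts = list(c("PostC", "sham")),
                          spots = sim$config$spot_ids, n_boot = 1000, seed = 1)
hits <- call_differential(res, threshold = 0.5,
                          reference_spot_id = sim$reference_spot_id)
nrow(hits)
#> [1] 26

net <- simulate_interactome(network_sim_config(
  c(10, 8, 8, rep(1, 34)), node_ids = sim$config$spot_ids, seed = 42))
ppi_enrichment(net$graph, hits$spot_id, n_permutations = 1000, seed = 1)
#> PPI enrichment: 26 nodes, 53 observed edges vs 16.63 expected
#>   (uniform null, 1000 permutations), p = 0.000999

part <- mcl(induce_network(net$graph, hits$spot_id), inflation = 1.4)
part
#> MCL partition: 26 nodes in 3 clusters (inflation 1.40, converged in 25 iterations)
#> cluster sizes: 16, 9, 1

ann <- simulate_annotations(default_planted_effects()$modules,
                            universe = sim$config$spot_ids,
                            n_decoy_terms = 20, seed = 42)
enrich_sets(tidy(part)$node[tidy(part)$cluster == 1], ann,
            annotated_universe(net$graph, ann))
#> # A tibble: ... (top rows)
#>   term_id      k     K strength    p_value       fdr
#> 1 NONMET       8     8    0.574 0.00000503 0.0000578
#> 2 OXPHOS       8     8    0.574 0.00000503 0.0000578
```

All 26 planted spots are recovered in this run; their subnetwork has 53
internal edges against 16.6 expected under the uniform null (p ≈ 1e-3,
the permutation minimum), MCL resolves three clusters, and the
overrepresentation table ranks the planted module terms first with
positive strength. `extend_regulatory()` + `screen_opposite_tfs()`
continue the chain, and `run_pipeline()` executes all stages at once,
writing every artifact (CSV/TSV/GMT/GraphML/JSON, all with commented
metadata headers) atomically and byte-reproducibly under one master seed.

Result types have `tidy()`, `glance()` and `autoplot()` methods.

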