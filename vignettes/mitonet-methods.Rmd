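---
title: "Models and methods behind mitonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

`mitonet` analyses small-replicate 2D-gel proteomic studies through a
network lens: normalize spot intensities, estimate bootstrap log
fold-change effect sizes, build and cluster the differential PPI network,
test pathway overrepresentation, and screen transcription factors for
opposite-regulation targets. This vignette documents the generative model,
the estimators, every tunable that matters, the numerical choices, and the
limits of what the synthetic validation shows.

## The generative model for spot tables

The simulator draws the intensity of spot $s$ on gel $g$ in group $G$ as

$$ I_{sg} \;=\; 2^{\,\mu_s \;+\; \beta_{sG} \;+\; \gamma_g \;+\; \varepsilon_{sg}}, \qquad
   \gamma_g \sim N(0, \sigma_{gel}^2),\;\;
   \varepsilon_{sg} \sim N(0, \sigma_{noise}^2). $$

* $\mu_s$ — baseline log2 abundance, fixed per spot. The albumin-like
  reference spot is forced to the highest baseline, as serum albumin
  dominates cardiac tissue gels.
* $\beta_{sG}$ — planted additive group effect in log2 units; the true
  log fold change between two groups is the difference of their
  $\beta$'s. The reference spot has $\beta = 0$ in every group.
* $\gamma_g$ — per-gel multiplicative loading scale, shared by every spot
  of a gel. This is the term albumin normalization exists to remove, and
  under this model it removes it *exactly* — that is why this minimal
  model was chosen.
* $\varepsilon_{sg}$ — per-observation log-normal noise, including on the
  reference spot. A consequence worth stating: after dividing by the
  reference, every normalized value inherits the reference spot's noise,
  so the effective per-value log2 SD is $\sqrt{2}\,\sigma_{noise}$, and the
  reference noise is shared (correlated) across all spots of a gel. This
  is a genuine property of single-reference-spot normalization, not an
  artifact of the simulator.

Defaults, chosen once as a realistic 2D-gel scenario and kept: 300 spots,
4 groups (`sham`, `Isch`, `I/R`, `PostC`), 3 gels per group (the scale of
a typical large-animal infarction study), $\sigma_{noise} = 0.25$
(≈ 17% CV, optimistic-realistic for fluorescent spot volumes across
biological replicates), $\sigma_{gel} = 1$ (loading differences up to
2-fold are common), and 26 planted spots at $|\log_2 FC| = 1$ arranged in
three functional modules: one responding only to post-conditioning, one
down-regulated by direct revascularization but up-regulated by
post-conditioning (hence opposite-regulated in the two
contrasts-vs-ischemia), and one mixing signs under post-conditioning.
The gel-to-gel SDs are free parameters of the generator, not calibrated
to any particular study.

Ground truth (effect table, cluster labels, opposite-TF list) is always
emitted next to the data so tests never re-derive it.

## Normalization and the bootstrap effect size

`normalize_spots()` divides every value by the reference spot of the same
gel; the reference row becomes exactly 1 and the operation is idempotent.
A missing or non-positive reference on any gel is an error naming the gel
— never a silent fallback.

`spot_logfc()` is the log2 ratio of group medians of normalized values,
exactly antisymmetric in its two groups. Zero medians are an error; no
pseudocount is ever applied silently.

`bootstrap_effect()` resamples gels with replacement independently within
each group (resample size = group size, since gels are the independent
biological units), recomputes the median-based logFC per replicate, and
summarises the distribution by its median (mirroring the median-based
point estimate) and a 95% percentile interval. Replicates whose resampled
median is zero are excluded and counted in `n_boot_used`; if all fail,
that is an error. Defaults: `n_boot = 1000`, log base 2 (the convention in
expression analysis; a `log_base` switch allows 10 for cross-checks), and
a differential threshold of 0.5 on the absolute effect size, applied
*strictly* (`> 0.5`, so exactly 0.5 is not differential). The threshold is
applied to the bootstrap effect size; the plain point estimate is reported
alongside for comparison.

### What n = 3 can and cannot do

With three gels per group the logFC estimator is a difference of
medians-of-3. Since the variance of the median of three normals is
$0.449\sigma^2$, the estimator SD is $\sqrt{2 \times 0.449}\,\sigma_{val}$
where $\sigma_{val}$ is the per-value SD after normalization
($\sqrt{2}\,\sigma_{noise}$ under the model above). At the default
$\sigma_{noise}=0.25$ this gives an estimator SD of ≈ 0.34 log2 units.
Two practical consequences, both visible in the test suite's measured
operating points:

* an individual effect estimate is frequently more than 0.3 away from the
  truth, even though it is nearly unbiased;
* a fixed call threshold of 0.5 lets a nontrivial fraction of true-null
  spots through (the tails of a 0.34-SD distribution), so the
  false-discovery proportion of the threshold rule is substantial at this
  noise level and replicate count. The pipeline reports sensitivity and
  FDP against ground truth so users can see this directly; interval
  under-coverage of the small-n percentile bootstrap (tested to stay
  within 80–100%) is expected rather than assumed nominal.

These are properties of the estimator at the study's scale, not
implementation defects; more gels, lower noise, or a higher threshold move
the operating point.

## Markov clustering

`mcl()` is a from-scratch dense-matrix implementation. Each internal
choice, all exposed as arguments and recorded in the result:

* **Self-loops** — per-column maximum incident edge weight (the standard
  stabilisation; isolated nodes get weight 1). Alternatives `"one"` and
  `"none"` are available.
* **Iteration** — expansion (matrix power, default 2) then inflation
  (entrywise power, default 1.4, then column renormalization), with
  entries below `pruning_threshold = 1e-5` zeroed (the per-column maximum
  is always kept so no column can empty) and convergence declared when
  the maximum entrywise change drops below `1e-8`, capped at 200
  iterations. Non-convergence returns a result with `converged = FALSE`
  plus a warning, never silently.
* **Cluster extraction** — attractors are rows with non-negligible
  diagonal mass (`> 1e-6`); attractors connected through non-zero entries
  form cluster cores; every node joins the clusters whose core rows
  overlap its column. A node attracted to several clusters goes to the
  largest, ties to the smallest cluster id — deterministic and documented.
  Labels are dense integers ordered by decreasing cluster size. Isolated
  nodes become singletons; disconnected components can never merge.

The test suite holds this implementation to an independently written
dense-matrix reference (no pruning, convergence at $10^{-12}$, loop-based
cluster extraction) on hundreds of random connected graphs at inflations
1.4 and 2.0, requiring identical partitions.

A behavioral note measured by the planted-partition tests: at inflation
1.4 MCL is deliberately coarse. On a 4×10-node planted partition with
within-cluster edge probability 0.5 and between probability 0.02, two
clusters joined by a couple of bridge edges are merged in roughly half of
random draws — an intrinsic granularity property of low inflation (an
independent implementation reproduces it), not noise in this code. Higher
inflation splits them at the cost of fragmenting sparser modules.

`network_modularity()` delegates to the standard weighted Newman
modularity (igraph) as a quality metric.

## PPI enrichment

The enrichment of a node set is tested by permutation: observed statistic
= edge count of the induced subgraph; null = edge counts of uniformly
sampled node sets of the same size; $p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$,
which is never below $1/(n_{perm}+1)$ and is exactly 1 for an edgeless or
whole-graph query. The uniform null answers "are these proteins more
connected than a random same-sized set?"; a degree-matched variant
(`null = "degree"`, decile bins) is available when degree composition
should be held fixed. Permutation counts of 1000 (default) keep the
p-value granularity at $10^{-3}$; calibration tests use 999 so that the
discrete p-grid does not coarsen rejection at $\alpha = 0.05$.

## Overrepresentation analysis

`hypergeom_test()` is the exact upper tail $P[X \ge k]$,
$X \sim \mathrm{Hypergeom}(N, K, n)$ — the one-sided Fisher test that
STRING-style enrichment tables report — computed by `phyper`, and verified
in tests against exhaustive enumeration from binomial coefficients for
every configuration up to $N = 12$. `strength` is
$\log_{10}((k/n)/(K/N))$, zero exactly when the query matches the
universe rate (and $-\infty$ when $k = 0$). BH-FDR is the classic step-up
with monotonicity, order-preserving, validated against a hand-computed
oracle. Choices:

* the universe defaults to the background-network nodes carrying at least
  one annotation (`annotated_universe()`), configurable and reported;
* query members outside the universe are dropped with a reported count;
* terms with no universe members are skipped rather than given $p = 1$,
  so they do not inflate the BH denominator.

No GO-graph propagation or gene-set permutation is attempted — terms are
flat sets.

## Regulatory extension and the opposite-regulation screen

`extend_regulatory()` adds TF nodes and directed TF→target edges for
targets present in the PPI network; TFs with no in-network target are
absent, PPI edges are untouched, and the operation is idempotent.
"Opposite regulation" — visually evident in node colorings of regulatory
subnetworks — is formalised as: target $t$ is opposite iff
$\mathrm{sign}(e_{I/R}(t)) \ne \mathrm{sign}(e_{PostC}(t))$ and both
$|e| >$ threshold (default 0.5, strict), where the two $e$'s are the
effect sizes in the two contrasts against ischemia. A TF is a candidate
when **at least one** in-network target is opposite; per-TF counts are
reported so stricter rules (e.g. *all* targets) can be applied
downstream. Candidates are ranked by opposite-target count, then id —
an invented but deterministic order. Targets missing an effect size in
either contrast are skipped with a warning, never treated as zero.

The linkset simulator plants `n_opposite_tfs` TFs whose in-network targets
all satisfy the predicate *under the true effect table*, and draws all
other TFs' targets from nodes that fail it, so the planted set is exactly
the screen's ground truth. In the orchestrated pipeline the planting
predicate uses half the planted effect magnitude as its cut — any value
below the planted magnitude selects the same pool — so the analysis
threshold can be varied freely without making the generator infeasible.
Screen exactness is therefore tested against the true effect tables; with
bootstrap-estimated effects at the default noise the screen inherits the
false-discovery behavior of the differential calls (a target with true
null effects shows estimated "opposite" effects in a few percent of
cases), which is the expected statistical price, not a logic error.

## File formats and reproducibility

Readers (spot CSV + gel-group TSV, STRING-dialect TSV, GMT, linkset TSV,
GraphML) reject rather than coerce, and every error message carries file
coordinates (line/row/column, offending identifier). The STRING dialect is
the public download format — integer `combined_score` 0–1000, default
cutoff 0.4 ("medium confidence"), duplicate pairs collapsed keeping the
maximum, self-pairs dropped. Identifier matching is exact and
case-sensitive; ortholog/alias mapping is assumed resolved upstream.
GraphML (rather than SIF) carries node attributes — kind, degree, cluster,
per-contrast effect sizes — and edge attributes (weight, ppi/regulatory
kind) with full fidelity.

`run_pipeline()` chains every stage under one master seed from which each
stage deterministically derives a sub-seed, writes each artifact via a
temp-file-then-rename, and stamps every text output with a commented
metadata header (tool version, configuration hash, seed — deliberately no
timestamps), so identical seeds give byte-identical artifact trees. An
unreachable threshold stops the pipeline cleanly after the differential
stage with an explanatory message. Configuration is one flat validated
list (`pipeline_config()`); unknown keys fail immediately.

## Problem sizes used in the validation suite

The suite exercises: 500 random connected graphs (≤ 7 nodes) for the MCL
oracle, 50 planted-partition draws (4 × 10 nodes) for recovery, the full
hypergeometric grid to N = 12, 200 fuzzed BH vectors, 100 simulated
datasets for effect-size recovery and 20 for the differential operating
point (300 spots each), 1000 permutation-test trials for calibration, 20
linkset draws for screen exactness, and two full pipeline replicates for
byte-level determinism — sizes picked to make the statistical assertions
stable at a few minutes of runtime.

## Known limitations

* The generator does not simulate 2D-gel image artifacts, spot-detection
  errors, saturation, or identification ambiguity; passing tests show the
  *statistics* behave as designed under the stated model, not that the
  model captures every failure mode of real gels.
* Three replicates per group fundamentally limit per-spot precision (see
  the estimator analysis above); the pipeline quantifies but cannot
  repair that.
* The permutation null is uniform by default; for hub-heavy differential
  sets the degree-matched option is the more conservative question.
* MCL granularity at inflation 1.4 merges weakly-bridged modules (see
  above); cluster counts should be read with the inflation value in mind.
* Live database clients (STRING, regulatory networks), identifier
  translation, and interactive visualization are out of scope — inputs
  are files in the documented dialects, outputs are tables and GraphML.
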