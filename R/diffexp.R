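#' Normalize spot intensities by the reference (albumin) spot
#'
#' Divides every spot's intensity by the intensity of the reference spot on
#' the same gel. Because gel-wide multiplicative loading effects act equally
#' on all spots of a gel, this single division removes them exactly; the
#' reference spot itself becomes 1 on every gel. Normalizing an
#' already-normalized table is a no-op.
#'
#' @param spots Long tibble with columns `spot_id`, `gel_id`, `group` and
#'   `intensity` (or `value`), e.g. from [read_spot_table()] or
#'   [simulate_spot_table()].
#' @param reference_spot_id Identifier of the reference spot; defaults to
#'   the `reference_spot_id` attribute of `spots` if present.
#' @return A tibble with columns `spot_id`, `gel_id`, `group`, `value`
#'   (dimensionless normalized intensity), carrying `reference_spot_id` as
#'   an attribute.
#' @examples
#' sim <- simulate_spot_table(spot_sim_config(n_spots = 5, seed = 1))
#' norm <- normalize_spots(sim$spots, sim$reference_spot_id)
#' all(norm$value[norm$spot_id == "ALB"] == 1)
#' @export
normalize_spots <- function(spots, reference_spot_id = attr(spots, "reference_spot_id")) {
  if (is.null(reference_spot_id)) {
    stop_mitonet("`reference_spot_id` must be given (or carried as an attribute).")
  }
  value_col <- if ("value" %in% names(spots)) "value" else "intensity"
  if (!all(c("spot_id", "gel_id", "group", value_col) %in% names(spots))) {
    stop_mitonet("`spots` needs columns spot_id, gel_id, group and intensity/value.")
  }
  ref <- spots |>
    filter(.data$spot_id == reference_spot_id) |>
    select("gel_id", ref = all_of(value_col))
  missing_gel <- setdiff(unique(spots$gel_id), ref$gel_id)
  if (length(missing_gel)) {
    stop_mitonet(sprintf("reference spot '%s' missing on gel '%s'.",
                         reference_spot_id, missing_gel[1]))
  }
  bad <- ref$gel_id[ref$ref <= 0 | is.na(ref$ref)]
  if (length(bad)) {
    stop_mitonet(sprintf("reference spot '%s' has non-positive intensity on gel '%s'.",
                         reference_spot_id, bad[1]))
  }
  out <- spots |>
    left_join(ref, by = "gel_id") |>
    mutate(value = .data[[value_col]] / .data$ref) |>
    select("spot_id", "gel_id", "group", "value")
  attr(out, "reference_spot_id") <- reference_spot_id
  out
}

group_values <- function(norm, spot, grp) {
  v <- norm$value[norm$spot_id == spot & norm$group == grp]
  if (length(v) == 0L) {
    stop_mitonet(sprintf("no gels for spot '%s' in group '%s'.", spot, grp))
  }
  v
}

#' Median-based log fold change between two groups
#'
#' The log fold change of a spot between two groups is the log (base 2 by
#' default) of the ratio of the group medians of its normalized
#' intensities. It is exactly antisymmetric in the two groups. A zero
#' median is an error: no pseudocount is silently applied.
#'
#' @param norm Normalized table from [normalize_spots()].
#' @param spot Spot identifier.
#' @param group_a,group_b Numerator and denominator group labels.
#' @param log_base Logarithm base (default 2).
#' @return A single number, `log(median_a / median_b, log_base)`.
#' @export
spot_logfc <- function(norm, spot, group_a, group_b, log_base = 2) {
  ma <- stats::median(group_values(norm, spot, group_a))
  mb <- stats::median(group_values(norm, spot, group_b))
  if (ma <= 0 || mb <= 0) {
    stop_mitonet(sprintf(
      "zero or negative median for spot '%s' (%s: %g, %s: %g); no pseudocount is applied.",
      spot, group_a, ma, group_b, mb
    ))
  }
  log_ratio(ma / mb, log_base)
}

# log2/log10 keep exact values on exact power-of-base ratios
log_ratio <- function(x, base) {
  if (base == 2) log2(x) else if (base == 10) log10(x) else log(x, base = base)
}

# bootstrap core shared by bootstrap_effect()/bootstrap_effects(): resample
# gels with replacement independently within each group, recompute the
# median-ratio logFC per replicate
boot_replicates <- function(va, vb, n_boot, log_base) {
  med_a <- boot_medians(va, n_boot)
  med_b <- boot_medians(vb, n_boot)
  ok <- med_a > 0 & med_b > 0
  list(logfc = log_ratio(med_a[ok] / med_b[ok], log_base),
       n_failed = sum(!ok))
}

# medians of n_boot with-replacement resamples of x; vectorized closed
# forms for the small group sizes typical of gel replicates
boot_medians <- function(x, n_boot) {
  n <- length(x)
  X <- matrix(x[sample.int(n, n_boot * n, replace = TRUE)], n_boot, n)
  if (n == 2L) {
    (X[, 1] + X[, 2]) / 2
  } else if (n == 3L) {
    rowSums(X) - pmax(X[, 1], X[, 2], X[, 3]) - pmin(X[, 1], X[, 2], X[, 3])
  } else if (n == 4L) {
    (rowSums(X) - do.call(pmax, asplit(X, 2)) - do.call(pmin, asplit(X, 2))) / 2
  } else {
    apply(X, 1L, stats::median)
  }
}

#' Bootstrap the logFC effect size of one spot
#'
#' Resamples gels with replacement independently within each group
#' (resample size = group size), recomputes the median-based log fold
#' change on each replicate, and summarises the bootstrap distribution by
#' its median (the effect size) and a percentile interval. Replicates where
#' a resampled group median is zero are recorded as failed and excluded.
#'
#' @inheritParams spot_logfc
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed; the same seed reproduces the result
#'   exactly.
#' @param conf_level Coverage of the percentile interval (default 0.95).
#' @param threshold Differential-call threshold on the absolute effect size
#'   (default 0.5); the comparison is strict (`>`).
#' @return A one-row tibble: `spot_id`, `contrast`, `logfc_point`,
#'   `effect_size`, `ci_low`, `ci_high`, `n_boot`, `n_boot_used`,
#'   `is_differential`.
#' @examples
#' sim <- simulate_spot_table(spot_sim_config(n_spots = 5, seed = 1))
#' norm <- normalize_spots(sim$spots, sim$reference_spot_id)
#' bootstrap_effect(norm, "S001", "PostC", "sham", n_boot = 200, seed = 1)
#' @export
bootstrap_effect <- function(norm, spot, group_a, group_b,
                             n_boot = 1000, seed = 1L,
                             conf_level = 0.95, threshold = 0.5,
                             log_base = 2) {
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  check_scalar_number(conf_level, "conf_level", min = 0, strict_min = TRUE)
  va <- group_values(norm, spot, group_a)
  vb <- group_values(norm, spot, group_b)
  if (length(va) < 2L || length(vb) < 2L) {
    stop_mitonet(sprintf(
      "bootstrap needs >= 2 gels per group for spot '%s' (got %d vs %d).",
      spot, length(va), length(vb)
    ))
  }
  point <- spot_logfc(norm, spot, group_a, group_b, log_base = log_base)
  reps <- withr::with_seed(seed, boot_replicates(va, vb, n_boot, log_base))
  if (length(reps$logfc) == 0L) {
    stop_mitonet(sprintf("all bootstrap replicates failed for spot '%s'.", spot))
  }
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(reps$logfc, c(alpha, 1 - alpha)))
  eff <- stats::median(reps$logfc)
  tibble(
    spot_id = spot,
    contrast = paste(group_a, "vs", group_b),
    logfc_point = point,
    effect_size = eff,
    ci_low = ci[1],
    ci_high = ci[2],
    n_boot = n_boot,
    n_boot_used = length(reps$logfc),
    is_differential = abs(eff) > threshold
  )
}

#' Bootstrap effect sizes for all spots and contrasts
#'
#' Tidy driver over [bootstrap_effect()]: one row per spot and contrast.
#' Per-(spot, contrast) sub-seeds are derived deterministically from the
#' master seed, so any single result can be reproduced in isolation.
#'
#' @inheritParams bootstrap_effect
#' @param contrasts List of 2-vectors `c(numerator, denominator)` of group
#'   labels.
#' @param spots Spot identifiers to process; defaults to every spot in
#'   `norm`.
#' @return A tibble of class `mito_diffexp`, rows sorted by contrast then
#'   spot id.
#' @export
bootstrap_effects <- function(norm, contrasts,
                              spots = NULL,
                              n_boot = 1000, seed = 1L,
                              conf_level = 0.95, threshold = 0.5,
                              log_base = 2) {
  if (is.null(spots)) spots <- sort(unique(norm$spot_id))
  if (!length(contrasts)) stop_mitonet("`contrasts` must be non-empty.")
  grid <- tidyr::expand_grid(ci = seq_along(contrasts), spot = spots)
  seeds <- spawn_seeds(seed, nrow(grid))
  out <- purrr::pmap_dfr(
    list(grid$ci, grid$spot, seeds),
    function(ci, spot, s) {
      bootstrap_effect(norm, spot, contrasts[[ci]][1], contrasts[[ci]][2],
                       n_boot = n_boot, seed = s, conf_level = conf_level,
                       threshold = threshold, log_base = log_base)
    }
  ) |>
    arrange(.data$contrast, .data$spot_id)
  attr(out, "log_base") <- log_base
  attr(out, "threshold") <- threshold
  class(out) <- c("mito_diffexp", class(out))
  out
}

#' Call differential spots from bootstrap results
#'
#' A spot is differential in a contrast when the absolute bootstrap effect
#' size strictly exceeds the threshold. The reference spot, if named, is
#' always excluded.
#'
#' @param results Tibble from [bootstrap_effects()] (needs `spot_id`,
#'   `contrast`, `effect_size`).
#' @param threshold Positive threshold on |effect size| (default 0.5,
#'   strict comparison).
#' @param reference_spot_id Optional reference spot to exclude.
#' @return A tibble of differential calls (`spot_id`, `contrast`,
#'   `effect_size`); the union across contrasts is
#'   `unique(out$spot_id)`.
#' @export
call_differential <- function(results, threshold = 0.5, reference_spot_id = NULL) {
  check_scalar_number(threshold, "threshold", min = 0, strict_min = TRUE)
  out <- as_tibble(results) |>
    filter(abs(.data$effect_size) > threshold) |>
    select("spot_id", "contrast", "effect_size")
  if (!is.null(reference_spot_id)) {
    out <- filter(out, .data$spot_id != reference_spot_id)
  }
  out
}

#' Write bootstrap differential results as TSV
#'
#' @param results Tibble from [bootstrap_effects()].
#' @param path Output path.
#' @param header Extra metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_diffexp <- function(results, path, header = character()) {
  cols <- c("spot_id", "contrast", "logfc_point", "effect_size",
            "ci_low", "ci_high", "n_boot", "n_boot_used", "is_differential")
  write_tsv_atomic(as_tibble(results)[cols], path, header = header)
}
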