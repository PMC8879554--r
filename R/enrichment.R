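#' Upper-tail hypergeometric test
#'
#' Exact probability of observing `k` or more annotated members in a query
#' of size `n`, when `K` of the `N` universe members carry the annotation:
#' `P[X >= k]` for `X ~ Hypergeom(N, K, n)` (the one-sided Fisher test).
#' Vectorized over its arguments.
#'
#' @param k Annotated members of the query set.
#' @param K Annotated members of the universe.
#' @param n Query set size.
#' @param N Universe size.
#' @return Exact p-value(s) in (0, 1].
#' @examples
#' hypergeom_test(5, 5, 5, 20) # = 1 / choose(20, 5)
#' @export
hypergeom_test <- function(k, K, n, N) {
  ok <- is.numeric(k) & is.numeric(K) & is.numeric(n) & is.numeric(N)
  if (!all(ok)) stop_mitonet("all of k, K, n, N must be numeric.")
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  bad <- k < 0 | k > pmin(n, K) | K > N | n > N
  if (any(bad)) {
    i <- which(bad)[1]
    stop_mitonet(sprintf(
      "invalid hypergeometric bounds: k=%g, K=%g, n=%g, N=%g (need 0 <= k <= min(n, K), K <= N, n <= N).",
      k[i], K[i], n[i], N[i]
    ))
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# minimal common-length recycling
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, rep_len, length.out = len)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with monotonicity enforcement; order-preserving
#' (the i-th output corresponds to the i-th input). Inputs outside \[0, 1\]
#' are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted values (FDR) of the same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop_mitonet("`p` must be numeric.")
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_mitonet("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overrepresentation analysis of a node set
#'
#' Tests each annotation term for overrepresentation in a query set
#' against a universe, STRING-style: exact upper-tail hypergeometric
#' p-values, BH-FDR across all tested terms, and a `strength` column
#' `log10((k/n) / (K/N))`, the log10 ratio of observed to expected
#' annotated fraction. Query members outside the universe are dropped
#' (with a reported count); terms without universe members are skipped so
#' they do not dilute the FDR correction.
#'
#' @param query_set Character vector of query identifiers.
#' @param annotations Annotation tibble (`term_id`, `description`,
#'   `members` list-column), e.g. from [read_gmt()] or
#'   [simulate_annotations()].
#' @param universe Character vector of background identifiers.
#' @return Tibble of class `mito_enrichment`, one row per tested term with
#'   columns `term_id`, `description`, `k`, `K`, `n`, `N`, `strength`,
#'   `p_value`, `fdr`, sorted by p-value then term id. The number of query
#'   members dropped is attached as attribute `n_dropped`.
#' @examples
#' ann <- tibble::tibble(term_id = "T1", description = "d",
#'                       members = list(c("A", "B", "C")))
#' enrich_sets(c("A", "B"), ann, universe = c(LETTERS[1:10]))
#' @export
enrich_sets <- function(query_set, annotations, universe) {
  if (length(universe) == 0L) stop_mitonet("`universe` must be non-empty.")
  universe <- unique(as.character(universe))
  query_all <- unique(as.character(query_set))
  query <- intersect(query_all, universe)
  n_dropped <- length(query_all) - length(query)
  if (n_dropped > 0L) {
    rlang::inform(sprintf("%d query member(s) outside the universe dropped.", n_dropped))
  }
  if (length(query) == 0L) {
    stop_mitonet("no query member lies in the universe.")
  }
  N <- length(universe)
  n <- length(query)
  rows <- annotations |>
    mutate(
      K = vapply(.data$members, function(m) length(intersect(m, universe)), 0L),
      k = vapply(.data$members, function(m) length(intersect(m, query)), 0L)
    ) |>
    filter(.data$K > 0L) |>
    select("term_id", "description", "k", "K")
  if (nrow(rows) == 0L) {
    stop_mitonet("no annotation term has members in the universe.")
  }
  out <- rows |>
    mutate(
      n = n, N = N,
      strength = log10((.data$k / n) / (.data$K / N)),
      p_value = hypergeom_test(.data$k, .data$K, n, N),
      fdr = bh_fdr(.data$p_value)
    ) |>
    arrange(.data$p_value, .data$term_id)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("mito_enrichment", class(out))
  out
}

#' Write an overrepresentation table as TSV
#'
#' @param enrichment Tibble from [enrich_sets()] (possibly with extra
#'   grouping columns such as `cluster`).
#' @param path Output path.
#' @param header Extra metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(enrichment, path, header = character()) {
  write_tsv_atomic(as_tibble(enrichment), path, header = header)
}
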