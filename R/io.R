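#' @importFrom readr read_lines write_lines
NULL

# metadata header written at the top of every text artifact; deliberately
# timestamp-free so identical runs are byte-identical
metadata_header <- function(seed = NULL, config_hash = NULL, extra = character()) {
  c(
    sprintf("# mitonet %s", pkg_version()),
    if (!is.null(config_hash)) sprintf("# config_hash: %s", config_hash),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    extra
  )
}

# atomic write: serialize to <path>.tmp then rename into place
write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  readr::write_lines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop_mitonet(sprintf("could not move temporary file into place at '%s'.", path))
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path, header = character()) {
  body <- c(
    paste(names(df), collapse = "\t"),
    do.call(paste, c(lapply(df, format_field), sep = "\t"))
  )
  if (nrow(df) == 0L) body <- body[1]
  write_atomic(c(header, body), path)
}

format_field <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    format(x, digits = 15, trim = TRUE, scientific = FALSE)
  } else {
    as.character(x)
  }
}

#' Read a spot-intensity table
#'
#' Reads a rectangular CSV of raw spot intensities (first column `spot_id`,
#' one column per gel) together with a two-column gel-to-group TSV, and
#' validates the result: intensities must be numeric and non-negative, spot
#' and gel identifiers unique, every gel mapped to a group, and the
#' reference spot present with strictly positive intensity on every gel.
#' Lines starting with `#` are metadata comments and are skipped.
#'
#' @param csv_path Path to the intensity CSV.
#' @param group_map_path Path to the TSV mapping `gel_id` to `group`.
#' @param reference_spot_id Identifier of the albumin-like reference spot.
#' @return A long tibble with columns `spot_id`, `gel_id`, `group`,
#'   `intensity`, carrying the reference spot id as attribute
#'   `reference_spot_id`.
#' @seealso [write_spot_table()], [normalize_spots()]
#' @export
read_spot_table <- function(csv_path, group_map_path, reference_spot_id) {
  for (p in c(csv_path, group_map_path)) {
    if (!file.exists(p)) stop_mitonet(sprintf("file not found: '%s'.", p))
  }
  lines <- readr::read_lines(csv_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) < 2L) stop_mitonet(sprintf("'%s': no data rows.", csv_path))
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncol <- length(cells[[1]])
  if (ncol < 2L) stop_mitonet(sprintf("'%s': need a spot_id column plus gels.", csv_path))
  if (any(lengths(cells) != ncol)) {
    bad <- which(lengths(cells) != ncol)[1]
    stop_mitonet(sprintf("'%s': row %d is not rectangular.", csv_path, bad))
  }
  gel_ids <- cells[[1]][-1]
  if (anyDuplicated(gel_ids)) stop_mitonet(sprintf("'%s': duplicate gel ids.", csv_path))
  spot_ids <- vapply(cells[-1], `[[`, "", 1L)
  if (anyDuplicated(spot_ids)) {
    stop_mitonet(sprintf("'%s': duplicate spot id '%s'.",
                         csv_path, spot_ids[duplicated(spot_ids)][1]))
  }
  vals <- matrix(NA_real_, length(spot_ids), length(gel_ids),
                 dimnames = list(spot_ids, gel_ids))
  for (i in seq_along(spot_ids)) {
    v <- suppressWarnings(as.numeric(cells[[i + 1L]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop_mitonet(sprintf(
        "'%s': non-numeric intensity at row %d (spot '%s'), column %d (gel '%s').",
        csv_path, i + 1L, spot_ids[i], j + 1L, gel_ids[j]
      ))
    }
    vals[i, ] <- v
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop_mitonet(sprintf("negative intensity for spot '%s' on gel '%s'.",
                         spot_ids[idx[1]], gel_ids[idx[2]]))
  }
  if (!reference_spot_id %in% spot_ids) {
    stop_mitonet(sprintf("reference spot '%s' not found in '%s'.",
                         reference_spot_id, csv_path))
  }
  if (any(vals[reference_spot_id, ] <= 0)) {
    g <- gel_ids[which(vals[reference_spot_id, ] <= 0)[1]]
    stop_mitonet(sprintf("reference spot '%s' is not positive on gel '%s'.",
                         reference_spot_id, g))
  }
  gmap <- read_two_col_tsv(group_map_path, c("gel_id", "group"))
  missing_gel <- setdiff(gel_ids, gmap$gel_id)
  if (length(missing_gel)) {
    stop_mitonet(sprintf("gel '%s' has no group in '%s'.",
                         missing_gel[1], group_map_path))
  }
  out <- tibble(
    spot_id = rep(spot_ids, times = length(gel_ids)),
    gel_id = rep(gel_ids, each = length(spot_ids)),
    intensity = as.vector(vals)
  ) |>
    left_join(gmap, by = "gel_id") |>
    select("spot_id", "gel_id", "group", "intensity")
  attr(out, "reference_spot_id") <- reference_spot_id
  out
}

read_two_col_tsv <- function(path, cols) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (length(cells) == 0L || !identical(cells[[1]][1:2], cols)) {
    stop_mitonet(sprintf("'%s': expected header '%s'.", path,
                         paste(cols, collapse = "\\t")))
  }
  bad <- which(lengths(cells) < 2L)
  if (length(bad)) stop_mitonet(sprintf("'%s': malformed line %d.", path, bad[1]))
  tibble(!!cols[1] := vapply(cells[-1], `[[`, "", 1L),
         !!cols[2] := vapply(cells[-1], `[[`, "", 2L))
}

#' Write a spot-intensity table and its gel-to-group map
#'
#' Inverse of [read_spot_table()]: writes the wide CSV (spots x gels) and
#' the two-column gel-to-group TSV, each preceded by a commented metadata
#' header. Writes are atomic (temp file, then rename).
#'
#' @param spots Long tibble with `spot_id`, `gel_id`, `group`, `intensity`
#'   (or `value`).
#' @param csv_path,group_map_path Output paths.
#' @param header Extra metadata comment lines (each starting with `#`).
#' @return The CSV path, invisibly.
#' @export
write_spot_table <- function(spots, csv_path, group_map_path, header = character()) {
  value_col <- if ("intensity" %in% names(spots)) "intensity" else "value"
  wide <- spots |>
    select("spot_id", "gel_id", value = all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "gel_id", values_from = "value")
  lines <- c(
    paste(names(wide), collapse = ","),
    do.call(paste, c(lapply(wide, format_field), sep = ","))
  )
  write_atomic(c(header, lines), csv_path)
  gmap <- distinct(spots, .data$gel_id, .data$group)
  write_tsv_atomic(gmap, group_map_path, header = header)
  invisible(csv_path)
}

#' Read a STRING-style interaction TSV into an interactome
#'
#' Parses the public STRING download dialect: a TSV (or space-separated)
#' file with columns `protein1`, `protein2`, `combined_score` (integer
#' 0-1000). Edges with `combined_score / 1000 >= score_cutoff` are kept;
#' duplicate pairs are collapsed keeping the maximum score; self-pairs are
#' dropped.
#'
#' @param tsv_path Path to the edge list.
#' @param score_cutoff Minimum confidence on the \[0, 1\] scale
#'   (default 0.4, STRING's "medium confidence").
#' @return An undirected simple [igraph][igraph::igraph-package] with edge
#'   attribute `weight` = combined score / 1000.
#' @export
read_string_tsv <- function(tsv_path, score_cutoff = 0.4) {
  if (!file.exists(tsv_path)) stop_mitonet(sprintf("file not found: '%s'.", tsv_path))
  check_scalar_number(score_cutoff, "score_cutoff", min = 0)
  lines <- readr::read_lines(tsv_path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  cells <- strsplit(lines, "[\t ]+")
  hdr <- cells[[1]]
  need <- c("protein1", "protein2", "combined_score")
  pos <- match(need, hdr)
  if (anyNA(pos)) {
    stop_mitonet(sprintf("'%s': header must contain %s.", tsv_path,
                         paste(need, collapse = ", ")))
  }
  rows <- cells[-1]
  nos <- line_no[-1]
  short <- which(lengths(rows) < max(pos))
  if (length(short)) {
    stop_mitonet(sprintf("'%s': malformed line %d.", tsv_path, nos[short[1]]))
  }
  p1 <- vapply(rows, `[[`, "", pos[1])
  p2 <- vapply(rows, `[[`, "", pos[2])
  sc <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", pos[3])))
  if (anyNA(sc)) {
    stop_mitonet(sprintf("'%s': malformed combined_score on line %d.",
                         tsv_path, nos[which(is.na(sc))[1]]))
  }
  if (any(sc < 0 | sc > 1000)) {
    stop_mitonet(sprintf("'%s': combined_score outside [0, 1000] on line %d.",
                         tsv_path, nos[which(sc < 0 | sc > 1000)[1]]))
  }
  edges <- tibble(p1 = p1, p2 = p2, score = sc) |>
    filter(.data$p1 != .data$p2) |>
    mutate(a = pmin(.data$p1, .data$p2), b = pmax(.data$p1, .data$p2)) |>
    group_by(.data$a, .data$b) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    filter(.data$score / 1000 >= score_cutoff)
  nodes <- sort(unique(c(p1, p2)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
    igraph::E(g)$weight <- edges$score / 1000
  }
  g
}

#' Write an interactome as a STRING-style TSV
#'
#' @param graph Undirected igraph with a `weight` edge attribute in
#'   \[0, 1\].
#' @param path Output path.
#' @param header Extra metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_string_tsv <- function(graph, path, header = character()) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  df <- tibble(
    protein1 = el[, 1], protein2 = el[, 2],
    combined_score = as.integer(round(w * 1000))
  )
  write_tsv_atomic(df, path, header = header)
}

#' Read a GMT annotation file
#'
#' Each line is `term<TAB>description<TAB>member1<TAB>member2...`. Terms
#' with no members, or duplicate term ids, are rejected with the offending
#' line number.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `term_id`, `description`, `members`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_mitonet(sprintf("file not found: '%s'.", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  nos <- which(keep)
  cells <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(cells) < 3L)
  if (length(bad)) {
    stop_mitonet(sprintf("'%s': line %d has no members.", path, nos[bad[1]]))
  }
  out <- tibble(
    term_id = vapply(cells, `[[`, "", 1L),
    description = vapply(cells, `[[`, "", 2L),
    members = lapply(cells, function(x) unique(x[-(1:2)]))
  )
  if (anyDuplicated(out$term_id)) {
    stop_mitonet(sprintf("'%s': duplicate term id '%s'.", path,
                         out$term_id[duplicated(out$term_id)][1]))
  }
  out
}

#' Write an annotation collection as GMT
#'
#' @param annotations Tibble with `term_id`, `description`, `members`.
#' @param path Output path.
#' @param header Extra metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path, header = character()) {
  if (any(lengths(annotations$members) == 0L)) {
    stop_mitonet("cannot write a term with an empty member set.")
  }
  lines <- purrr::pmap_chr(
    annotations[c("term_id", "description", "members")],
    function(term_id, description, members) {
      paste(c(term_id, description, members), collapse = "\t")
    }
  )
  write_atomic(c(header, lines), path)
}

#' Read a TF-to-target regulatory linkset TSV
#'
#' Expects a header containing `tf` and `target` (and optionally `source`).
#' Duplicate (tf, target) pairs are rejected with their line number.
#'
#' @param path Path to the linkset TSV.
#' @return A tibble with columns `tf`, `target`, `source`.
#' @export
read_linkset <- function(path) {
  if (!file.exists(path)) stop_mitonet(sprintf("file not found: '%s'.", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  nos <- which(keep)
  cells <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(cells) == 0L) stop_mitonet(sprintf("'%s': empty linkset.", path))
  hdr <- cells[[1]]
  pos <- match(c("tf", "target"), hdr)
  if (anyNA(pos)) {
    stop_mitonet(sprintf("'%s': header must contain 'tf' and 'target'.", path))
  }
  src_pos <- match("source", hdr)
  rows <- cells[-1]
  bad <- which(lengths(rows) < max(pos))
  if (length(bad)) {
    stop_mitonet(sprintf("'%s': malformed line %d.", path, nos[-1][bad[1]]))
  }
  out <- tibble(
    tf = vapply(rows, `[[`, "", pos[1]),
    target = vapply(rows, `[[`, "", pos[2]),
    source = if (!is.na(src_pos)) vapply(rows, `[[`, "", src_pos) else NA_character_
  )
  dup <- duplicated(out[c("tf", "target")])
  if (any(dup)) {
    stop_mitonet(sprintf("'%s': duplicate pair (%s, %s) on line %d.",
                         path, out$tf[dup][1], out$target[dup][1],
                         nos[-1][which(dup)[1]]))
  }
  out
}

#' Write a regulatory linkset TSV
#'
#' @param linkset Tibble with columns `tf`, `target` and optionally
#'   `source`.
#' @param path Output path.
#' @param header Extra metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_linkset <- function(linkset, path, header = character()) {
  if (anyDuplicated(linkset[c("tf", "target")])) {
    stop_mitonet("linkset contains duplicate (tf, target) pairs.")
  }
  if (!"source" %in% names(linkset)) linkset$source <- "unknown"
  write_tsv_atomic(linkset[c("tf", "target", "source")], path, header = header)
}

#' Export a network as GraphML
#'
#' Thin wrapper over igraph's GraphML writer that keeps all node and edge
#' attributes (log fold changes, degree, cluster id, node kind, edge kind,
#' weight) and prepends a metadata comment after the XML declaration. Writes
#' are atomic.
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @param header Extra metadata comment lines (each starting with `#`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, header = character()) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  igraph::write_graph(graph, tmp, format = "graphml")
  lines <- readr::read_lines(tmp)
  if (length(header)) {
    comment <- sprintf("<!-- %s -->", sub("^# ?", "", header))
    lines <- c(lines[1], comment, lines[-1])
  }
  readr::write_lines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop_mitonet(sprintf("could not move temporary file into place at '%s'.", path))
  }
  invisible(path)
}

#' Read a GraphML network
#'
#' @param path Path to a GraphML file.
#' @return An igraph object with its attributes.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop_mitonet(sprintf("file not found: '%s'.", path))
  igraph::read_graph(path, format = "graphml")
}
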