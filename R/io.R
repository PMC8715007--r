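#' Read a taxon abundance count table with its sample metadata
#'
#' Tables are TSV with samples in rows; the first column is the sample id.
#' An optional `--transpose`-style flag accommodates taxa-in-rows files.
#'
#' @param path TSV of integer counts, samples x taxa.
#' @param metadata_path TSV with columns `sample`, `subject`, `group`,
#'   `timepoint`.
#' @param transpose set `TRUE` if the file stores taxa in rows.
#' @return A list with `abundance` (tibble, `sample` + taxon columns,
#'   integer counts) and `metadata` (tibble).
#' @export
read_abundance_table <- function(path, metadata_path, transpose = FALSE) {
  ab <- read_wide_tsv(path, transpose = transpose)
  m <- feature_matrix(ab)
  bad <- which(m != floor(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-integer or negative count at sample '%s', taxon '%s' (value %s)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
      format(m[bad[1, , drop = FALSE]])))
  }
  meta <- read_metadata(metadata_path)
  missing <- setdiff(ab$sample, meta$sample)
  if (length(missing) > 0) {
    abort(sprintf("samples absent from metadata: %s",
                  paste(missing, collapse = ", ")))
  }
  ab <- mutate(ab, across(-"sample", as.integer))
  list(abundance = ab, metadata = meta)
}

#' Read a feature intensity table (metabolites or indicators)
#'
#' @inheritParams read_abundance_table
#' @return A tibble with a `sample` column and one numeric column per feature.
#' @export
read_feature_table <- function(path, transpose = FALSE) {
  tbl <- read_wide_tsv(path, transpose = transpose)
  m <- feature_matrix(tbl)
  if (any(!is.finite(m))) abort("feature table contains non-finite values")
  if (any(m < 0)) abort("feature table contains negative values")
  tbl
}

read_wide_tsv <- function(path, transpose = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()),
    progress = FALSE, name_repair = "minimal")
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in '%s' at row %d, column %d: expected %s",
                  path, probs$row[1], probs$col[1], probs$expected[1]))
  }
  names(raw)[1] <- "sample"
  if (transpose) {
    m <- feature_matrix(raw)
    raw <- matrix_to_tibble(t(m))
  }
  if (anyDuplicated(raw$sample)) {
    abort(sprintf("duplicate ids in '%s': %s", path,
                  paste(unique(raw$sample[duplicated(raw$sample)]),
                        collapse = ", ")))
  }
  if (anyDuplicated(names(raw))) abort(sprintf("duplicate column ids in '%s'", path))
  raw
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `subject`, `group`, `timepoint`.
#' @return A tibble; errors if required columns are missing, sample ids
#'   repeat, or a (subject, timepoint) pair appears twice.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), subject = readr::col_character(),
    group = readr::col_character(), timepoint = readr::col_double()),
    progress = FALSE)
  need <- c("sample", "subject", "group", "timepoint")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(sprintf("metadata lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample)) abort("duplicate sample ids in metadata")
  if (anyDuplicated(meta[c("subject", "timepoint")])) {
    abort("a (subject, timepoint) pair appears more than once in metadata")
  }
  meta[need]
}

#' Write a samples-x-features table as TSV
#'
#' @param tbl tibble with a `sample` id column.
#' @param path output path.
#' @export
write_feature_table <- function(tbl, path) {
  stopifnot("sample" %in% names(tbl))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a phylogenetic tree in newick format
#'
#' @param path file containing a single `;`-terminated newick string.
#' @return An [ape::read.tree()] `phylo` object; errors on malformed input,
#'   duplicate leaf labels or negative branch lengths.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl(";", txt, fixed = TRUE)) abort("newick string must end with ';'")
  if (lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE))) !=
      lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))) {
    abort("unbalanced parentheses in newick string")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) abort(sprintf("newick parse error: %s",
                                                     conditionMessage(e))))
  if (is.null(tree)) abort("newick parse error: unreadable tree")
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf labels in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("negative branch length in tree")
  }
  tree
}

#' Export a network as GraphML or an edge TSV
#'
#' Edge TSV columns: `source`, `target`, `source_type`, `target_type`,
#' `measure`, `score`, `sign`, `p`, `q`. Re-reading an edge TSV with
#' [read_network_edges()] reconstructs the edge multiset.
#'
#' @param network an `mm_network` (see [conet()], [tripartite_network()]).
#' @param path output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "graphml")) {
  if (!format[1] %in% c("edge_tsv", "graphml")) {
    abort(sprintf("unknown network format '%s'", format[1]))
  }
  format <- format[1]
  edges <- network_edge_frame(network)
  if (format == "edge_tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    nodes <- network$nodes
    g <- igraph::graph_from_data_frame(
      d = edges[c("source", "target", "measure", "score", "sign", "p", "q")],
      directed = FALSE,
      vertices = data.frame(name = nodes$node, type = nodes$type,
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

network_edge_frame <- function(network) {
  edges <- if (is.data.frame(network)) network else network$edges
  type_of <- function(ids) {
    if (!is.data.frame(network) && !is.null(network$nodes)) {
      network$nodes$type[match(ids, network$nodes$node)]
    } else rep(NA_character_, length(ids))
  }
  tibble(
    source = edges$source, target = edges$target,
    source_type = edges$source_type %||% type_of(edges$source),
    target_type = edges$target_type %||% type_of(edges$target),
    measure = edges$measure %||% "ensemble",
    score = edges$score, sign = edges$sign,
    p = edges$p, q = edges$q)
}

#' @rdname write_network
#' @return `read_network_edges()`: the edge tibble.
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(), target = readr::col_character(),
    source_type = readr::col_character(),
    target_type = readr::col_character(),
    measure = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}

#' Write / read a synthetic study and its ground truth
#'
#' `write_study()` lays a study out as the pipeline's on-disk contract:
#' `abundance.tsv`, `metabolites.tsv`, `indicators.tsv`, `metadata.tsv`,
#' `truth.json`, `config.json`.
#'
#' @param study an `mm_study`.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(study$abundance, file.path(dir, "abundance.tsv"))
  write_feature_table(study$metabolites, file.path(dir, "metabolites.tsv"))
  write_feature_table(study$indicators, file.path(dir, "indicators.tsv"))
  readr::write_tsv(study$metadata, file.path(dir, "metadata.tsv"),
                   progress = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", pretty = TRUE)
  cfg <- study$config
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(responsive_taxa = as_tibble(tr$responsive_taxa),
       mediating_metabolites = as_tibble(tr$mediating_metabolites),
       linked_indicators = unlist(tr$linked_indicators))
}

#' @rdname write_study
#' @export
read_study_config <- function(path) {
  do.call(study_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
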