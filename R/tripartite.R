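#' Tripartite taxon–metabolite–indicator correlation network
#'
#' Every cross-layer feature pair (taxon–metabolite, taxon–indicator,
#' metabolite–indicator) is tested with both Pearson and Spearman
#' correlation (analytic two-sided p from the t distribution on
#' \eqn{r\sqrt{(n-2)/(1-r^2)}}). BH correction is applied jointly across
#' all cross-layer tests; an edge is retained iff q < `q_threshold` for
#' BOTH methods with agreeing sign. Edge weight is the Spearman rho.
#'
#' @param taxa,metabolites,indicators samples-x-features tibbles, each
#'   with a `sample` column; joined on their shared samples (>= 4).
#' @param q_threshold joint BH q cut (default 0.05).
#' @return An `mm_network` with typed nodes and edges carrying `rho`
#'   (Spearman weight), `r` (Pearson), per-method p and q, and `sign`.
#' @export
tripartite_network <- function(taxa, metabolites, indicators,
                               q_threshold = 0.05) {
  layers <- list(taxon = taxa, metabolite = metabolites,
                 indicator = indicators)
  mats <- purrr::map(layers, feature_matrix)
  shared <- Reduce(intersect, purrr::map(mats, rownames))
  if (length(shared) < 4) abort("fewer than 4 shared samples across layers")
  mats <- purrr::map(mats, \(m) m[shared, , drop = FALSE])
  n <- length(shared)

  cor_p <- function(r) {
    r <- pmin(pmax(r, -1), 1)
    t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    2 * pt(-abs(t_stat), df = n - 2)
  }
  pair_tbl <- function(a, b, type_a, type_b) {
    r_p <- suppressWarnings(cor(mats[[a]], mats[[b]], method = "pearson"))
    r_s <- suppressWarnings(cor(mats[[a]], mats[[b]], method = "spearman"))
    tibble(source = rep(rownames(r_p), ncol(r_p)),
           target = rep(colnames(r_p), each = nrow(r_p)),
           source_type = type_a, target_type = type_b,
           r = as.vector(r_p), rho = as.vector(r_s),
           p_pearson = as.vector(cor_p(r_p)),
           p_spearman = as.vector(cor_p(r_s)))
  }
  tests <- bind_rows(
    pair_tbl("taxon", "metabolite", "taxon", "metabolite"),
    pair_tbl("taxon", "indicator", "taxon", "indicator"),
    pair_tbl("metabolite", "indicator", "metabolite", "indicator"))
  tests <- filter(tests, is.finite(.data$r), is.finite(.data$rho))

  # joint BH family: all cross-layer tests, both methods
  qs <- bh_adjust(c(tests$p_pearson, tests$p_spearman))
  k <- nrow(tests)
  tests$q_pearson <- qs[seq_len(k)]
  tests$q_spearman <- qs[k + seq_len(k)]

  edges <- tests |>
    filter(.data$q_pearson < q_threshold, .data$q_spearman < q_threshold,
           sign(.data$r) == sign(.data$rho), .data$rho != 0) |>
    mutate(sign = as.integer(sign(.data$rho)), score = .data$rho,
           measure = "pearson+spearman",
           p = pmax(.data$p_pearson, .data$p_spearman),
           q = pmax(.data$q_pearson, .data$q_spearman))
  nodes <- bind_rows(
    tibble(node = colnames(mats$taxon), type = "taxon"),
    tibble(node = colnames(mats$metabolite), type = "metabolite"),
    tibble(node = colnames(mats$indicator), type = "indicator"))
  structure(list(nodes = nodes, edges = edges, tests = tests,
                 params = list(q_threshold = q_threshold,
                               n_samples = n)),
            class = "mm_network")
}

#' Rank bridge metabolites in a tripartite network
#'
#' A metabolite is a bridge iff it carries at least one significant taxon
#' edge and at least one significant indicator edge — the nodes that tie
#' drug-responsive bacteria to host physiology. Bridges are ranked by
#' total degree, ties by summed |rho|, then lexicographic id.
#'
#' @param network an `mm_network` from [tripartite_network()].
#' @return A tibble: `metabolite`, `degree`, `taxon_degree`,
#'   `indicator_degree`, `sum_abs_rho`, `rank`.
#' @export
rank_bridge_metabolites <- function(network) {
  edges <- network$edges
  empty <- tibble(metabolite = character(0), degree = integer(0),
                  taxon_degree = integer(0), indicator_degree = integer(0),
                  sum_abs_rho = numeric(0), rank = integer(0))
  if (is.null(edges) || nrow(edges) == 0) return(empty)
  ends <- bind_rows(
    tibble(metabolite = edges$source, met_type = edges$source_type,
           other_type = edges$target_type, rho = edges$score),
    tibble(metabolite = edges$target, met_type = edges$target_type,
           other_type = edges$source_type, rho = edges$score)) |>
    filter(.data$met_type == "metabolite")
  if (nrow(ends) == 0) return(empty)
  ranked <- ends |>
    group_by(.data$metabolite) |>
    summarize(degree = n(),
              taxon_degree = sum(.data$other_type == "taxon"),
              indicator_degree = sum(.data$other_type == "indicator"),
              sum_abs_rho = sum(abs(.data$rho)), .groups = "drop") |>
    filter(.data$taxon_degree >= 1, .data$indicator_degree >= 1) |>
    arrange(desc(.data$degree), desc(.data$sum_abs_rho), .data$metabolite) |>
    mutate(rank = row_number())
  ranked
}
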