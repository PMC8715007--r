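#' Pairwise association scores between features
#'
#' Scores every feature pair under one of four measures. Samples (rows) are
#' first closed to proportions. Correlation measures are computed across
#' samples on the closed values; for the dissimilarity measures each
#' feature's cross-sample profile is additionally normalised to sum 1
#' (Bray–Curtis), or pseudocounted (1e-6) and renormalised before the
#' symmetrised Kullback–Leibler divergence
#' \eqn{\tfrac12[KL(p\|q) + KL(q\|p)]}.
#'
#' Feature pairs where a correlation is undefined (constant profile) are
#' returned as `NA` and reported in the `"skipped"` attribute.
#'
#' @param profiles samples-x-features tibble (with `sample` column) or
#'   matrix of relative abundances; at least 4 samples.
#' @param measure one of `"pearson"`, `"spearman"`, `"bray"`, `"kld"`.
#' @return Symmetric features-x-features score matrix.
#' @export
pairwise_scores <- function(profiles,
                            measure = c("pearson", "spearman", "bray", "kld")) {
  measure <- match.arg(measure)
  m <- if (is.data.frame(profiles)) feature_matrix(profiles) else as.matrix(profiles)
  if (nrow(m) < 4) abort("at least 4 samples required")
  m <- close_rows(m)
  skipped <- character(0)
  if (measure %in% c("pearson", "spearman")) {
    const <- apply(m, 2, function(v) sd(v) <= max(abs(v)) * 1e-12)
    skipped <- colnames(m)[const]
    s <- suppressWarnings(cor(m, method = measure))
    s[const, ] <- NA; s[, const] <- NA
    diag(s) <- ifelse(const, NA, 1)
  } else {
    prof <- sweep(m, 2, colSums(m), "/")   # per-feature profile closure
    zero_tot <- colSums(m) == 0
    skipped <- colnames(m)[zero_tot]
    if (measure == "bray") {
      n_f <- ncol(prof)
      s <- matrix(0, n_f, n_f, dimnames = list(colnames(m), colnames(m)))
      for (i in seq_len(n_f - 1)) {
        rest <- (i + 1):n_f
        s[i, rest] <- s[rest, i] <-
          1 - colSums(pmin(prof[, rest, drop = FALSE], prof[, i]))
      }
    } else {
      q <- sweep(prof + 1e-6, 2, colSums(prof + 1e-6), "/")
      lq <- log(q)
      # sym KL(p,q) = 1/2 [ sum p log p/q + sum q log q/p ]
      plogp <- colSums(q * lq)
      cross <- crossprod(q, lq)   # cross[i, j] = sum_s q_i log q_j
      s <- 0.5 * (outer(plogp, rep(1, ncol(q))) - cross +
                    outer(rep(1, ncol(q)), plogp) - t(cross))
      dimnames(s) <- list(colnames(m), colnames(m))
      diag(s) <- 0
    }
    s[zero_tot, ] <- NA; s[, zero_tot] <- NA
  }
  attr(s, "skipped") <- skipped
  attr(s, "measure") <- measure
  s
}

#' Select candidate edges from a score matrix
#'
#' Per measure, the `top_n` highest-scoring and `bottom_n` lowest-scoring
#' feature pairs become candidates. For correlation measures the top tail
#' is co-presence (+1) and the bottom tail exclusion (-1); for
#' dissimilarity measures small scores indicate co-presence and large
#' scores exclusion. Ties are broken by lexicographic pair id so candidate
#' sets are deterministic.
#'
#' @param scores matrix from [pairwise_scores()].
#' @param top_n,bottom_n tail sizes (defaults 1000 and 1000); when fewer
#'   pairs exist every pair lands in both tails.
#' @return Tibble of candidates: `source`, `target`, `measure`, `score`,
#'   `sign`, `tail`.
#' @export
select_candidates <- function(scores, top_n = 1000, bottom_n = 1000) {
  measure <- attr(scores, "measure") %||% "score"
  ut <- upper.tri(scores)
  idx <- which(ut & is.finite(scores), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(source = character(0), target = character(0),
                  measure = character(0), score = numeric(0),
                  sign = integer(0), tail = character(0)))
  }
  pair_id <- paste(rownames(scores)[idx[, 1]], colnames(scores)[idx[, 2]],
                   sep = "\r")
  sc <- scores[idx]
  ord_desc <- order(-sc, pair_id)
  ord_asc <- order(sc, pair_id)
  n_pair <- length(sc)
  top <- ord_desc[seq_len(min(top_n, n_pair))]
  bottom <- ord_asc[seq_len(min(bottom_n, n_pair))]
  dissim <- measure %in% c("bray", "kld")
  mk <- function(sel, tail) {
    tibble(source = rownames(scores)[idx[sel, 1]],
           target = colnames(scores)[idx[sel, 2]],
           measure = measure, score = sc[sel],
           sign = if (dissim) {
             if (tail == "top") -1L else 1L
           } else {
             if (tail == "top") 1L else -1L
           },
           tail = tail)
  }
  bind_rows(mk(top, "top"), mk(bottom, "bottom"))
}

#' Permutation significance and bootstrap stability of candidate edges
#'
#' For each candidate edge, a permutation null is built by shuffling one
#' feature's sample labels per iteration; with `renormalize = TRUE`
#' (recommended for taxon–taxon edges) samples are re-closed to proportions
#' after each shuffle so the null preserves compositional structure
#' (ReBoot-style). Two-sided p = `(1 + #extreme) / (iterations + 1)`,
#' where extremeness is measured on the score for correlations and on the
#' null-mean-centered score for the nonnegative dissimilarity measures.
#' Bootstrap resampling of samples (with replacement) gives a 2.5–97.5%
#' interval of the score; edges whose interval covers the null expectation
#' are flagged unstable.
#'
#' One permutation set and one bootstrap set, drawn from R's RNG at `seed`,
#' are shared across edges of a call, making results deterministic given
#' `(data, candidates, iterations, seed)`.
#'
#' @param profiles samples-x-features tibble or matrix of relative
#'   abundances.
#' @param candidates candidate tibble from [select_candidates()] (columns
#'   `source`, `target`, `measure`, `score`, `sign`).
#' @param iterations permutation and bootstrap iterations (>= 100).
#' @param renormalize re-close samples after each shuffle.
#' @param seed integer seed.
#' @return `candidates` with columns `p`, `boot_lo`, `boot_hi`, `unstable`
#'   appended.
#' @export
edge_significance <- function(profiles, candidates, iterations = 1000,
                              renormalize = TRUE, seed = 1L) {
  if (iterations < 100) abort("iterations must be at least 100 (null too coarse)")
  m <- if (is.data.frame(profiles)) feature_matrix(profiles) else as.matrix(profiles)
  m <- close_rows(m)
  n <- nrow(m)
  set.seed(substream_seed(seed, "edge_significance"))
  perm <- vapply(seq_len(iterations), function(i) sample.int(n), integer(n))
  boot <- matrix(sample.int(n, n * iterations, replace = TRUE), nrow = n)
  measure_code <- c(pearson = 1L, spearman = 2L, bray = 3L, kld = 4L)

  out <- candidates
  if (nrow(candidates) == 0) {
    out$p <- numeric(0); out$boot_lo <- numeric(0)
    out$boot_hi <- numeric(0); out$unstable <- logical(0)
    return(out)
  }
  res <- cpp_edge_significance(
    m,
    match(candidates$source, colnames(m)),
    match(candidates$target, colnames(m)),
    unname(measure_code[candidates$measure]),
    candidates$score, perm, boot, renormalize)
  out$p <- res[, 1]
  out$boot_lo <- res[, 2]
  out$boot_hi <- res[, 3]
  out$unstable <- res[, 4] == 1
  out
}

#' Merge per-measure significant edges into a final network
#'
#' Benjamini–Hochberg correction is applied within each measure across its
#' candidates; an edge enters the final network iff it passes
#' `q < q_threshold` in at least `min_support` measures with a consistent
#' sign. Edges whose supporting measures disagree in sign are dropped and
#' reported in the `"dropped"` attribute. The combined p is Fisher's
#' combination across supporting measures.
#'
#' @param edges tibble from [edge_significance()] pooled over measures.
#' @param q_threshold per-measure BH q cut (default 0.05).
#' @param min_support minimum number of supporting measures (default 2).
#' @return Tibble of final edges: `source`, `target`, `sign`, `support`,
#'   `combined_p`, `measures`, `score` (mean score over supporting
#'   correlation measures, else first supporting measure's score).
#' @export
consolidate_edges <- function(edges, q_threshold = 0.05, min_support = 2) {
  if (nrow(edges) == 0) {
    out <- tibble(source = character(0), target = character(0),
                  sign = integer(0), support = integer(0),
                  combined_p = numeric(0), measures = character(0),
                  score = numeric(0))
    attr(out, "dropped") <- out[0, c("source", "target")]
    return(out)
  }
  edges <- edges |>
    group_by(.data$measure) |>
    mutate(q = bh_adjust(.data$p)) |>
    ungroup()
  sig <- filter(edges, .data$q < q_threshold)
  merged <- sig |>
    group_by(.data$source, .data$target) |>
    summarize(
      support = n(),
      sign_ok = n_distinct(.data$sign) == 1,
      sign = .data$sign[1],
      combined_p = pchisq(-2 * sum(log(pmax(.data$p, 1e-300))),
                          df = 2 * n(), lower.tail = FALSE),
      measures = paste(sort(.data$measure), collapse = ","),
      score = if (any(.data$measure %in% c("pearson", "spearman"))) {
        mean(.data$score[.data$measure %in% c("pearson", "spearman")])
      } else .data$score[1],
      .groups = "drop")
  conflicted <- filter(merged, .data$support >= min_support, !.data$sign_ok)
  out <- merged |>
    filter(.data$support >= min_support, .data$sign_ok) |>
    select(-"sign_ok") |>
    arrange(desc(.data$support), .data$combined_p, .data$source, .data$target)
  attr(out, "dropped") <- conflicted[c("source", "target")]
  out
}

#' Ensemble co-occurrence network over taxa
#'
#' The full CoNet-style chain: prevalence filter, per-sample closure to
#' relative abundances, candidate edges from the top/bottom tails of four
#' association measures (Pearson, Spearman, Bray–Curtis, symmetrised KL),
#' renormalized-permutation significance with bootstrap stability, BH
#' within measure, and a sign-consistent multi-measure merge.
#'
#' @param abundance samples-x-taxa count tibble with a `sample` column.
#' @param metadata metadata tibble (used for the per-condition filter).
#' @param top_n,bottom_n candidate tail sizes per measure.
#' @param iterations permutation/bootstrap iterations.
#' @param q_threshold,min_support merge parameters, see
#'   [consolidate_edges()].
#' @param min_sum,min_occurrence prevalence filter, see
#'   [filter_features()].
#' @param renormalize renormalized (compositional) permutation null.
#' @param seed integer seed.
#' @return An object of class `mm_network`: `nodes` (tibble `node`,
#'   `type`), `edges` (final edge tibble with `source_type`/`target_type`),
#'   plus the filtered taxon set and parameters in `params`.
#' @export
conet <- function(abundance, metadata, top_n = 1000, bottom_n = 1000,
                  iterations = 1000, q_threshold = 0.05, min_support = 2,
                  min_sum = 120, min_occurrence = 12, renormalize = TRUE,
                  seed = 1L) {
  filtered <- filter_features(abundance, metadata, min_sum = min_sum,
                              min_occurrence = min_occurrence)
  rel <- close_rows(feature_matrix(filtered))
  cands <- purrr::map(c("pearson", "spearman", "bray", "kld"), function(me) {
    select_candidates(pairwise_scores(rel, me), top_n, bottom_n)
  }) |> bind_rows()
  scored <- edge_significance(rel, cands, iterations = iterations,
                              renormalize = renormalize, seed = seed)
  final <- consolidate_edges(scored, q_threshold = q_threshold,
                             min_support = min_support)
  nodes <- tibble(node = colnames(rel), type = "taxon")
  edges <- final |>
    mutate(source_type = "taxon", target_type = "taxon",
           measure = .data$measures, p = .data$combined_p,
           q = .data$combined_p)
  structure(list(
    nodes = nodes, edges = edges, candidates = scored,
    params = list(top_n = top_n, bottom_n = bottom_n,
                  iterations = iterations, q_threshold = q_threshold,
                  min_support = min_support, min_sum = min_sum,
                  min_occurrence = min_occurrence,
                  renormalize = renormalize, seed = seed)),
    class = "mm_network")
}

#' @export
print.mm_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat(sprintf("<mm_network> %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", tt, names(tt)), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}
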