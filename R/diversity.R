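#' Per-sample alpha diversity
#'
#' Computes, for each sample, bias-corrected Chao1 richness
#' \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} (singletons \eqn{F_1}, doubletons
#' \eqn{F_2}), Shannon entropy \eqn{H = -\sum p_i \ln p_i} in nats,
#' Gini–Simpson diversity \eqn{1 - \sum p_i^2}, and Shannon evenness
#' \eqn{H / \ln S_{obs}} (0 when a single taxon is observed). No
#' rarefaction is applied; depth normalisation, where wanted, is the
#' caller's job.
#'
#' @param counts a samples-x-taxa tibble with a `sample` column (or a
#'   count matrix with sample rownames, or a single sample's count vector).
#' @return A tibble with columns `sample`, `observed`, `chao1`, `shannon`,
#'   `simpson`, `evenness`.
#' @export
alpha_diversity <- function(counts) {
  m <- as_count_matrix(counts)
  if (any(m < 0) || any(m != floor(m))) {
    abort("alpha diversity requires nonnegative integer counts")
  }
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(sprintf("all-zero sample(s): %s",
                  paste(rownames(m)[zero], collapse = ", ")))
  }
  s_obs <- rowSums(m > 0)
  f1 <- rowSums(m == 1)
  f2 <- rowSums(m == 2)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- vegan::diversity(m, index = "shannon")
  simpson <- vegan::diversity(m, index = "simpson")
  evenness <- ifelse(s_obs > 1, shannon / log(s_obs), 0)
  tibble(sample = rownames(m), observed = as.numeric(s_obs),
         chao1 = as.numeric(chao1), shannon = as.numeric(shannon),
         simpson = as.numeric(simpson), evenness = as.numeric(evenness))
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    feature_matrix(counts)
  } else if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      rownames(counts) <- sprintf("sample_%d", seq_len(nrow(counts)))
    }
    counts
  } else {
    matrix(counts, nrow = 1, dimnames = list("sample_1", NULL))
  }
}

#' Bray–Curtis dissimilarity between two samples
#'
#' \eqn{1 - 2\sum_i \min(x_i, y_i) / (\sum x + \sum y)}, in \[0, 1\].
#'
#' @param x,y nonnegative count or proportion vectors of equal length,
#'   each with a positive sum.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) abort("vectors must be nonnegative")
  if (sum(x) <= 0 || sum(y) <= 0) abort("each vector needs a positive sum")
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Unweighted UniFrac distance between two communities
#'
#' Fraction of the branch length observed in either community that leads
#' exclusively to leaves of one community; branches subtending no observed
#' leaf are excluded. Backed by [picante::unifrac()].
#'
#' @param presence_x,presence_y named presence vectors (or character
#'   vectors of taxon labels) giving the taxa observed in each community.
#' @param tree a rooted `phylo` tree with branch lengths covering all
#'   observed taxa.
#' @export
unweighted_unifrac <- function(presence_x, presence_y, tree) {
  lab_x <- presence_labels(presence_x)
  lab_y <- presence_labels(presence_y)
  absent <- setdiff(union(lab_x, lab_y), tree$tip.label)
  if (length(absent) > 0) {
    abort(sprintf("taxa absent from tree: %s", paste(absent, collapse = ", ")))
  }
  if (setequal(lab_x, lab_y)) return(0)
  if (!ape::is.rooted(tree)) tree <- ape::multi2di(tree, random = FALSE)
  univ <- tree$tip.label
  comm <- rbind(x = as.numeric(univ %in% lab_x),
                y = as.numeric(univ %in% lab_y))
  colnames(comm) <- univ
  as.numeric(picante::unifrac(comm, tree))
}

presence_labels <- function(v) {
  if (is.character(v)) return(unique(v))
  if (is.null(names(v))) abort("presence vectors must be named by taxon")
  names(v)[v > 0]
}

#' Sample-by-sample distance matrix
#'
#' @param counts samples-x-taxa tibble (with `sample` column) or matrix.
#' @param method `"bray"` or `"unifrac"` (unweighted).
#' @param tree required for UniFrac.
#' @return A symmetric distance matrix with sample dimnames.
#' @export
beta_diversity <- function(counts, method = c("bray", "unifrac"),
                           tree = NULL) {
  method <- match.arg(method)
  m <- as_count_matrix(counts)
  if (method == "bray") {
    d <- as.matrix(vegan::vegdist(m, method = "bray"))
  } else {
    if (is.null(tree)) abort("unweighted UniFrac requires a tree")
    if (!ape::is.rooted(tree)) tree <- ape::multi2di(tree, random = FALSE)
    absent <- setdiff(colnames(m), tree$tip.label)
    if (length(absent) > 0) {
      abort(sprintf("taxa absent from tree: %s",
                    paste(absent, collapse = ", ")))
    }
    d <- as.matrix(picante::unifrac((m > 0) * 1, tree))
    d <- d[rownames(m), rownames(m)]
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers \eqn{-\tfrac12 d^2}, eigendecomposes, and scales
#' eigenvectors by the square roots of positive eigenvalues. Negative
#' eigenvalues are reported but contribute no axes (no Lingoes/Cailliez
#' correction); the proportion explained is computed over positive
#' eigenvalues only.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param n_axes number of axes to return (at most samples - 1).
#' @return An object of class `mm_pcoa`: list with `coordinates` (tibble:
#'   `sample`, `axis_1` ...), `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    abort("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) abort("distance matrix must have zero diagonal")
  n <- nrow(d)
  if (n_axes > n - 1) abort("n_axes must be at most samples - 1")
  ids <- rownames(d) %||% sprintf("sample_%d", seq_len(n))
  g <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% g %*% ctr
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  k <- min(n_axes, sum(pos))
  coords <- matrix(0, n, n_axes)
  if (k > 0) {
    coords[, seq_len(k)] <-
      e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  }
  colnames(coords) <- sprintf("axis_%d", seq_len(n_axes))
  prop <- rep(0, n_axes)
  if (any(pos)) prop[seq_len(k)] <- e$values[seq_len(k)] / sum(e$values[pos])
  structure(list(
    coordinates = bind_cols(tibble(sample = ids), as_tibble(coords)),
    eigenvalues = e$values,
    proportion_explained = prop), class = "mm_pcoa")
}

#' @export
print.mm_pcoa <- function(x, ...) {
  cat(sprintf("<mm_pcoa> %d samples, %d axes (%s of positive inertia)\n",
              nrow(x$coordinates), ncol(x$coordinates) - 1L,
              paste(sprintf("%.1f%%", 100 * x$proportion_explained),
                    collapse = " + ")))
  invisible(x)
}
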