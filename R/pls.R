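#' Fit a two-class PLS-DA model (NIPALS PLS1)
#'
#' Predictors are autoscaled (centered, unit variance) and the class label
#' coded as a centered +/-1 response; components are extracted by NIPALS
#' with deflation of the predictor matrix after each component. For a
#' univariate response the inner NIPALS loop converges in one pass, but the
#' general loop (tolerance 1e-10, at most 500 iterations) is kept so the
#' fit generalises. Zero-variance predictors are retained with zero weight
#' (they carry no class information).
#'
#' @param x numeric matrix or samples-x-features tibble (with a `sample`
#'   column) of predictors.
#' @param y two-class vector (factor, character or numeric) of length
#'   `nrow(x)`.
#' @param n_components number of latent components (default 2), at most
#'   `min(p, n - 1)`.
#' @return An object of class `mm_plsda`: weights `w` (p x A), predictor
#'   loadings `p_load`, response loadings `c_load`, scores `t_scores`
#'   (n x A), per-component explained response sum of squares `ssy`,
#'   preprocessing constants (`x_center`, `x_scale`, `y_center`), feature
#'   and class labels.
#' @export
plsda_fit <- function(x, y, n_components = 2) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) abort("PLS-DA requires exactly two classes")
  if (any(table(y) < 2)) abort("each class needs at least 2 samples")
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) abort("length(y) must equal nrow(x)")
  if (n_components > min(p, n - 1)) {
    abort("n_components must be at most min(p, n - 1)")
  }
  features <- colnames(x) %||% sprintf("feature_%d", seq_len(p))

  x_center <- colMeans(x)
  x_scale <- apply(x, 2, sd)
  x_scale[x_scale == 0] <- 1   # constant predictors stay centered at 0
  xs <- scale(x, center = x_center, scale = x_scale)
  y_num <- ifelse(y == levels(y)[2], 1, -1)
  y_center <- mean(y_num)
  u0 <- y_num - y_center

  w <- matrix(0, p, n_components)
  p_load <- matrix(0, p, n_components)
  c_load <- numeric(n_components)
  t_scores <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  e <- xs
  f <- u0
  for (a in seq_len(n_components)) {
    u <- f
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(500)) {
      wa <- drop(crossprod(e, u))
      nw <- sqrt(sum(wa^2))
      if (!is.finite(nw) || nw < 1e-300) {
        abort(sprintf("component %d: degenerate weights (response unexplained)", a))
      }
      wa <- wa / nw
      ta <- drop(e %*% wa)
      ca <- drop(crossprod(f, ta)) / sum(ta^2)
      u_new <- f / ca
      if (sqrt(sum((ta - t_old)^2)) < 1e-10 * sqrt(sum(ta^2))) {
        converged <- TRUE
        break
      }
      t_old <- ta
      u <- u_new
    }
    if (!converged) abort(sprintf("NIPALS failed to converge in component %d", a))
    pa <- drop(crossprod(e, ta)) / sum(ta^2)
    w[, a] <- wa; p_load[, a] <- pa; c_load[a] <- ca; t_scores[, a] <- ta
    ssy[a] <- ca^2 * sum(ta^2)
    e <- e - tcrossprod(ta, pa)
    f <- f - ta * ca
  }
  rownames(w) <- rownames(p_load) <- features
  structure(list(
    w = w, p_load = p_load, c_load = c_load, t_scores = t_scores,
    ssy = ssy, n_components = n_components, n_features = p,
    features = features, classes = levels(y),
    x_center = x_center, x_scale = x_scale, y_center = y_center),
    class = "mm_plsda")
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\lVert w_a \rVert)^2 / \sum_a SSY_a}}
#' where \eqn{SSY_a} is the response sum of squares explained by component
#' \eqn{a} and \eqn{p} the number of predictors. \eqn{\sum_j VIP_j^2 = p}
#' for every model.
#'
#' @param model an `mm_plsda` fit.
#' @return Named numeric vector of per-feature VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "mm_plsda"))
  if (sum(model$ssy) <= 0) abort("response unexplained: all SSY are zero")
  wn <- sweep(model$w, 2, sqrt(colSums(model$w^2)), "/")
  num <- drop(wn^2 %*% model$ssy)
  setNames(sqrt(model$n_features * num / sum(model$ssy)), model$features)
}

#' @export
print.mm_plsda <- function(x, ...) {
  cat(sprintf("<mm_plsda> %d features, %d components (%s vs %s)\n",
              x$n_features, x$n_components, x$classes[1], x$classes[2]))
  cat(sprintf("  explained response SS per component: %s\n",
              paste(signif(x$ssy, 3), collapse = ", ")))
  invisible(x)
}

#' Tidy a PLS-DA fit: one row per feature per component
#'
#' @param x an `mm_plsda` fit.
#' @param ... unused.
#' @method tidy mm_plsda
#' @export
tidy.mm_plsda <- function(x, ...) {
  vip <- vip_scores(x)
  tidyr::expand_grid(component = seq_len(x$n_components),
                     feature = x$features) |>
    mutate(weight = as.vector(x$w),
           loading = as.vector(x$p_load)) |>
    left_join(tibble(feature = names(vip), vip = unname(vip)),
              by = "feature") |>
    select("feature", "component", "weight", "loading", "vip") |>
    arrange(.data$component, .data$feature)
}

#' One-row model summary of a PLS-DA fit
#'
#' @param x an `mm_plsda` fit.
#' @param ... unused.
#' @method glance mm_plsda
#' @export
glance.mm_plsda <- function(x, ...) {
  tibble(n_features = x$n_features, n_components = x$n_components,
         ssy_total = sum(x$ssy),
         ssy_first = x$ssy[1])
}
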