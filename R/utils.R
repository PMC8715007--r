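#' @importFrom rlang .data abort warn inform
#' @importFrom stats cor median rnorm rmultinom rlnorm runif sd wilcox.test
#'   lm coef pchisq pt qt quantile setNames
#' @importFrom utils head
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom generics tidy glance
#' @useDynLib microrev, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Convert a samples-x-features tibble (first column = sample id) to a
# numeric matrix with sample rownames.  All feature tables in the package
# travel in this wide tibble form.
feature_matrix <- function(tbl, id_col = "sample") {
  stopifnot(is.data.frame(tbl))
  if (!id_col %in% names(tbl)) {
    abort(sprintf("table must carry a '%s' identifier column", id_col))
  }
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (!is.numeric(m)) abort("feature columns must all be numeric")
  rownames(m) <- ids
  m
}

matrix_to_tibble <- function(m, id_col = "sample") {
  tibble::as_tibble(m, rownames = id_col)
}

# Close each row (sample) to proportions.
close_rows <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(sprintf("sample(s) with non-positive total: %s",
                  paste(rownames(m)[rs <= 0], collapse = ", ")))
  }
  sweep(m, 1, rs, "/")
}

# Deterministic per-stage substream seed derived from one global seed, so
# that pipeline stages can be re-run in isolation reproducibly.  Kept
# strictly below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-exported generics
#'
#' `tidy()` / `glance()` from \pkg{generics} and `autoplot()` from
#' \pkg{ggplot2}, re-exported so methods work without attaching those
#' packages.
#' @name reexports
#' @keywords internal
#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname reexports
#' @importFrom generics glance
#' @export
generics::glance

#' @rdname reexports
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
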