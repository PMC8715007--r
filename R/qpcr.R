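#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 copy number:
#' `Ct = intercept + slope * log10(copies)`. Amplification efficiency is
#' `E = 10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' -3.32193 and E = 1 (100%). A non-negative slope yields a fit object
#' flagged as an invalid assay.
#'
#' @param log10_copies log10 template copy numbers (>= 3 distinct points).
#' @param ct observed Ct values, same length.
#' @return An object of class `mm_standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `valid`.
#' @export
fit_standard_curve <- function(log10_copies, ct) {
  if (length(log10_copies) != length(ct)) abort("inputs must have equal length")
  if (length(unique(log10_copies)) < 3) {
    abort("at least 3 distinct dilution points required")
  }
  if (sd(log10_copies) == 0) abort("zero variance in log10 copies")
  fit <- lm(ct ~ log10_copies)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(
    slope = slope, intercept = intercept, r_squared = r2,
    efficiency = if (slope < 0) 10^(-1 / slope) - 1 else NA_real_,
    valid = slope < 0), class = "mm_standard_curve")
}

#' @export
print.mm_standard_curve <- function(x, ...) {
  cat(sprintf(
    "<mm_standard_curve> Ct = %.3f %+.4f * log10(copies); R2 = %.4f; E = %s%s\n",
    x$intercept, x$slope, x$r_squared,
    if (is.na(x$efficiency)) "NA" else sprintf("%.1f%%", 100 * x$efficiency),
    if (x$valid) "" else "  [INVALID ASSAY: slope >= 0]"))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x an `mm_standard_curve`.
#' @param ... unused.
#' @method tidy mm_standard_curve
#' @export
tidy.mm_standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @method glance mm_standard_curve
#' @export
glance.mm_standard_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, efficiency = x$efficiency,
         valid = x$valid)
}

#' Absolute quantification against a standard curve
#'
#' `copies = 10^((ct - intercept) / slope)`; at `ct == intercept` the
#' template held exactly one copy.
#'
#' @param ct Ct value(s).
#' @param curve a valid `mm_standard_curve`.
#' @return Copy number(s).
#' @export
quantify_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "mm_standard_curve"))
  if (!curve$valid) abort("invalid standard curve (slope >= 0)")
  10^((ct - curve$intercept) / curve$slope)
}

#' Validate drug-responsive taxa from absolute copy numbers
#'
#' A candidate taxon is responsive iff the two-sided Wilcoxon rank-sum test
#' between the disease and treated groups rejects at `alpha`, and the
#' treated median lies strictly closer to the control median than the
#' disease median does (movement back toward the healthy state, not merely
#' any shift).
#'
#' @param copies long tibble with columns `taxon`, `group`, `copies`.
#' @param groups length-3 character: control, disease, treated.
#' @param alpha significance level (default 0.05).
#' @return A tibble: `taxon`, `p`, `direction` (`"reduced"` when treatment
#'   lowers the copy number, `"increased"` otherwise), `responsive`.
#' @export
validate_responsive <- function(copies, groups = c("WT", "Tg", "TgR"),
                                alpha = 0.05) {
  need <- c("taxon", "group", "copies")
  if (!all(need %in% names(copies))) {
    abort("copies must have columns taxon, group, copies")
  }
  copies |>
    group_by(.data$taxon) |>
    group_modify(function(d, key) {
      gs <- split(d$copies, factor(d$group, levels = groups))
      if (any(lengths(gs[groups[2:3]]) < 3)) {
        abort(sprintf("taxon '%s': disease and treated groups need >= 3 measurements",
                      key$taxon))
      }
      if (length(gs[[groups[1]]]) == 0) {
        abort(sprintf("taxon '%s': missing control group", key$taxon))
      }
      mc <- median(gs[[groups[1]]]); md <- median(gs[[groups[2]]])
      mt <- median(gs[[groups[3]]])
      exact <- all(lengths(gs[groups[2:3]]) <= 10)
      p <- suppressWarnings(
        wilcox.test(gs[[groups[2]]], gs[[groups[3]]], exact = exact)$p.value)
      tibble(p = p,
             direction = if (mt < md) "reduced" else "increased",
             responsive = p < alpha && abs(mt - mc) < abs(md - mc))
    }) |>
    ungroup()
}
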