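#' Abundance-based taxon filter
#'
#' A taxon is kept iff, within at least one condition, its count sum is at
#' least `min_sum` and it occurs (count > 0) in at least `min_occurrence`
#' samples. The conventional prevalence filter applied before co-occurrence
#' network inference.
#'
#' @param abundance samples-x-taxa count tibble with a `sample` column.
#' @param grouping either a vector of condition labels (one per sample, in
#'   table order) or a metadata tibble with `sample` plus a condition
#'   column named by `condition`.
#' @param min_sum,min_occurrence thresholds (defaults 120 and 12).
#' @param condition name of the grouping column when `grouping` is a
#'   metadata tibble (default `"group"`).
#' @return The filtered table, with the discarded taxon ids in attribute
#'   `"discarded"`.
#' @export
filter_features <- function(abundance, grouping, min_sum = 120,
                            min_occurrence = 12, condition = "group") {
  m <- feature_matrix(abundance)
  cond <- condition_labels(grouping, rownames(m), condition)
  split_idx <- split(seq_len(nrow(m)), cond)
  if (any(lengths(split_idx) == 0)) abort("empty condition in grouping")
  keep <- rep(FALSE, ncol(m))
  for (idx in split_idx) {
    sums <- colSums(m[idx, , drop = FALSE])
    occ <- colSums(m[idx, , drop = FALSE] > 0)
    keep <- keep | (sums >= min_sum & occ >= min_occurrence)
  }
  out <- abundance[c("sample", colnames(m)[keep])]
  attr(out, "discarded") <- colnames(m)[!keep]
  out
}

condition_labels <- function(grouping, sample_ids, condition = "group") {
  if (is.data.frame(grouping)) {
    if (!all(c("sample", condition) %in% names(grouping))) {
      abort(sprintf("grouping table needs columns 'sample' and '%s'", condition))
    }
    idx <- match(sample_ids, grouping$sample)
    if (anyNA(idx)) {
      abort(sprintf("samples missing from grouping: %s",
                    paste(sample_ids[is.na(idx)], collapse = ", ")))
    }
    grp <- grouping[[condition]][idx]
    if (is.factor(grp)) grp else as.character(grp)
  } else {
    if (length(grouping) != length(sample_ids)) {
      abort("grouping vector must have one label per sample")
    }
    if (is.factor(grouping)) grouping else as.character(grouping)
  }
}

#' Total-ion-intensity normalisation
#'
#' Divides every feature value by its sample's total so each sample row
#' sums to 1 — the standard normalisation for LC-MS feature tables.
#'
#' @param features samples-x-features tibble with a `sample` column.
#' @return The normalised tibble.
#' @export
total_ion_normalize <- function(features) {
  m <- feature_matrix(features)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(sprintf("zero-total sample(s): %s",
                  paste(rownames(m)[tot <= 0], collapse = ", ")))
  }
  matrix_to_tibble(sweep(m, 1, tot, "/"))
}

#' Two-group differential screen: PLS-DA VIP plus rank-sum test
#'
#' Fits a two-class PLS-DA (default 2 components) on the feature table,
#' computes per-feature VIP, a two-sided Wilcoxon rank-sum p per feature
#' (exact null for group sizes up to 10 without ties, tie-corrected normal
#' approximation otherwise), and Benjamini–Hochberg q across the screen. A
#' feature is selected iff VIP exceeds `vip_threshold` and, when a
#' `p_threshold` is given, p falls below it. Direction is the sign of
#' median(second group) - median(first group).
#'
#' @param features samples-x-features tibble with a `sample` column.
#' @param metadata tibble with `sample` and the grouping column.
#' @param groups length-2 character: reference group first (e.g. control),
#'   comparison group second (e.g. disease).
#' @param vip_threshold VIP cut (0.7 for taxa, 1.0 for metabolites in the
#'   pipeline defaults).
#' @param p_threshold optional p cut; `NULL` disables the p clause.
#' @param n_components PLS-DA components.
#' @param condition grouping column name in `metadata`.
#' @return A tibble of screen records: `feature`, `vip`, `p`, `q`,
#'   `direction` (+1 comparison > reference median, -1 below, 0 tie),
#'   `selected`.
#' @export
differential_screen <- function(features, metadata, groups,
                                vip_threshold = 1, p_threshold = 0.05,
                                n_components = 2, condition = "group") {
  m <- feature_matrix(features)
  cond <- condition_labels(metadata, rownames(m), condition)
  if (length(groups) != 2) abort("exactly two groups required")
  in_scope <- cond %in% groups
  m <- m[in_scope, , drop = FALSE]
  cond <- cond[in_scope]
  sizes <- table(factor(cond, levels = groups))
  if (any(sizes < 2)) {
    abort(sprintf("group(s) with fewer than 2 samples: %s",
                  paste(groups[sizes < 2], collapse = ", ")))
  }
  y <- factor(cond, levels = groups)
  vip <- tryCatch(vip_scores(plsda_fit(m, y, n_components = n_components)),
                  error = function(e) {
                    # degenerate designs (e.g. identical groups) explain no
                    # response variance: no feature is important
                    setNames(rep(0, ncol(m)), colnames(m))
                  })

  a <- m[y == groups[1], , drop = FALSE]
  b <- m[y == groups[2], , drop = FALSE]
  exact <- nrow(a) <= 10 && nrow(b) <= 10
  p <- vapply(seq_len(ncol(m)), function(j) {
    if (sd(m[, j]) == 0) return(1)
    suppressWarnings(
      wilcox.test(b[, j], a[, j], exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  q <- bh_adjust(p)
  med_diff <- apply(b, 2, median) - apply(a, 2, median)
  direction <- sign(med_diff)
  selected <- vip > vip_threshold &
    (if (is.null(p_threshold)) TRUE else p < p_threshold)
  tibble(feature = colnames(m), vip = unname(vip), p = p, q = q,
         direction = as.integer(direction), selected = unname(selected))
}

#' Trend consistency across timepoints
#'
#' A feature is trend-consistent iff it is selected at every timepoint and
#' its direction is identical and nonzero at every timepoint — the
#' longitudinal intersection that separates progression-linked features
#' from one-off hits.
#'
#' @param screens named list of per-timepoint screen tibbles from
#'   [differential_screen()] (names = timepoint labels).
#' @return A tibble: `feature`, one `direction_<t>` column per timepoint,
#'   `consistent`, `overall_direction` (0 when not consistent). A feature
#'   missing from a timepoint's screen counts as not selected there.
#' @export
trend_consistency <- function(screens) {
  if (length(screens) < 2) abort("at least 2 timepoints required")
  if (is.null(names(screens)) || any(names(screens) == "")) {
    names(screens) <- paste0("t", seq_along(screens))
  }
  long <- purrr::imap(screens, \(s, tp)
                      mutate(s[c("feature", "direction", "selected")],
                             timepoint = tp)) |>
    bind_rows()
  universe <- unique(long$feature)
  wide_dir <- long |>
    select("feature", "timepoint", "direction") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "direction",
                       names_prefix = "direction_")
  per_feat <- long |>
    group_by(.data$feature) |>
    summarize(
      n_selected = sum(.data$selected),
      same_dir = n_distinct(.data$direction) == 1 &&
        all(.data$direction != 0),
      dir1 = .data$direction[1], .groups = "drop") |>
    mutate(consistent = .data$n_selected == length(screens) & .data$same_dir,
           overall_direction = ifelse(.data$consistent, .data$dir1, 0L))
  wide_dir |>
    left_join(per_feat[c("feature", "consistent", "overall_direction")],
              by = "feature") |>
    mutate(consistent = tidyr::replace_na(.data$consistent, FALSE),
           overall_direction = as.integer(
             tidyr::replace_na(.data$overall_direction, 0))) |>
    arrange(match(.data$feature, universe))
}

#' Treatment-reversal screen
#'
#' A feature shows a treatment-dependent (reversed) trend iff, at every
#' post-treatment timepoint, the treated group's median lies strictly
#' closer to the control median than the disease median does:
#' `|median(treated) - median(control)| < |median(disease) - median(control)|`.
#'
#' @param features samples-x-features tibble with a `sample` column.
#' @param metadata tibble with `sample`, `group`, `timepoint`.
#' @param candidate_features feature ids to assess (e.g. the
#'   trend-consistent set); defaults to all.
#' @param groups length-3 character: control, disease, treated.
#' @param treatment_timepoints timepoints at which the treated group has
#'   received treatment.
#' @return A tibble: `feature`, one `shrinkage_<t>` column per treatment
#'   timepoint (|treated - control| / |disease - control| medians; < 1
#'   means movement toward control), and `reversed`.
#' @export
reversal_screen <- function(features, metadata, candidate_features = NULL,
                            groups = c("WT", "Tg", "TgR"),
                            treatment_timepoints = NULL) {
  m <- feature_matrix(features)
  meta <- metadata[match(rownames(m), metadata$sample), ]
  if (anyNA(meta$sample)) abort("metadata must cover every sample")
  if (is.null(treatment_timepoints)) {
    tps <- sort(unique(meta$timepoint))
    if (length(tps) < 2) abort("need at least 2 timepoints")
    treatment_timepoints <- tps[-1]
  }
  feats <- candidate_features %||% colnames(m)
  miss <- setdiff(feats, colnames(m))
  if (length(miss) > 0) {
    abort(sprintf("candidate features absent from table: %s",
                  paste(miss, collapse = ", ")))
  }
  res <- purrr::map(treatment_timepoints, function(tp) {
    sel <- meta$timepoint == tp
    grp <- meta$group[sel]
    if (!all(groups %in% grp)) {
      abort(sprintf("missing group at timepoint %s", format(tp)))
    }
    sub <- m[sel, feats, drop = FALSE]
    med <- function(g) apply(sub[grp == g, , drop = FALSE], 2, median)
    mc <- med(groups[1]); md <- med(groups[2]); mt <- med(groups[3])
    shr <- abs(mt - mc) / abs(md - mc)   # Inf/NaN when disease == control
    tibble(feature = feats, timepoint = tp, shrinkage = shr,
           reversed_here = abs(mt - mc) < abs(md - mc))
  }) |> bind_rows()
  res |>
    tidyr::pivot_wider(id_cols = "feature", names_from = "timepoint",
                       values_from = c("shrinkage", "reversed_here"),
                       names_glue = "{.value}_{timepoint}") |>
    mutate(reversed = purrr::pmap_lgl(
      across(starts_with("reversed_here_")), \(...) all(...))) |>
    select(-starts_with("reversed_here_"))
}

#' Benjamini–Hochberg step-up adjusted p-values
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
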