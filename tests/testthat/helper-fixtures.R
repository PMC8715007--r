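# Small study used across tests: 30 taxa, 40 metabolites, quick to draw.
small_config <- function(seed = 1L, ...) {
  study_config(n_taxa = 30, n_metabolites = 40, n_indicators = 5,
               n_responsive_taxa = 3, n_mediating_metabolites = 3,
               library_size_mean = 5000, seed = seed, ...)
}

# Wide tibble from a named matrix.
wide_tbl <- function(m, ids = rownames(m)) {
  tibble::as_tibble(m, rownames = NULL) |>
    dplyr::mutate(sample = ids, .before = 1)
}

# Independent step-up BH oracle: for each i, scan the whole tail.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Direct-formula VIP oracle, coded independently of vip_scores():
# per-feature loop over components, no matrix algebra shared with the
# implementation.
vip_direct <- function(model) {
  p <- model$n_features
  A <- model$n_components
  tot <- sum(model$ssy)
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(A)) {
      wnorm <- sqrt(sum(model$w[, a]^2))
      acc <- acc + model$ssy[a] * (model$w[j, a] / wnorm)^2
    }
    out[j] <- sqrt(p * acc / tot)
  }
  out
}

# Relative-abundance tibble of a study.
study_rel_abundance <- function(study) {
  m <- microrev:::close_rows(microrev:::feature_matrix(study$abundance))
  microrev:::matrix_to_tibble(m)
}

# Run the screening chain (screens -> trends) on one study layer.
run_screens <- function(tbl, metadata, groups, vip, p_cut) {
  tps <- sort(unique(metadata$timepoint))
  setNames(lapply(tps, function(tp) {
    keep <- metadata$sample[metadata$timepoint == tp]
    differential_screen(dplyr::filter(tbl, sample %in% keep), metadata,
                        groups = groups, vip_threshold = vip,
                        p_threshold = p_cut)
  }), as.character(tps))
}
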