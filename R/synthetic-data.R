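#' Configuration for a synthetic longitudinal multi-omics study
#'
#' Defines the design of a three-group (control / disease / treated)
#' longitudinal study with planted drug-responsive taxa, mediating
#' metabolites and linked physiological indicators. Defaults mirror a
#' typical rodent intervention study: 6 subjects per group sampled at 8, 9
#' and 10 months of age, 100 taxa, 300 metabolite features and 11
#' indicators, with 5 responsive taxa and 5 mediating metabolites planted.
#'
#' The disease effect is multiplicative and age-dependent: a planted taxon's
#' expected abundance in the disease group is multiplied by
#' `disease_effect^(t+1)` at timepoint index `t` (0, 1, 2), in the planted
#' direction. Treatment starts after the first sampling, so the treated
#' group carries the full disease effect at the first timepoint and a
#' residual `(1 - reversal_fraction)` scaled effect at the two
#' post-treatment timepoints.
#'
#' @param n_subjects_per_group subjects per group (default 6).
#' @param groups ordered labels for control, disease, treated.
#' @param timepoints ordered numeric timepoint labels (months of age).
#' @param n_taxa,n_metabolites,n_indicators layer sizes.
#' @param n_responsive_taxa,n_mediating_metabolites planted feature counts.
#' @param disease_effect multiplicative fold change per timepoint step (> 0).
#' @param reversal_fraction fraction of the disease effect undone by
#'   treatment, in \[0, 1\].
#' @param library_size_mean,library_size_dispersion mean and log-scale sd of
#'   the per-sample sequencing depth (log-normal).
#' @param taxon_base_logmean_sd sd of per-taxon baseline log-abundance.
#' @param metabolite_noise_sd,indicator_noise_sd residual noise scales on
#'   the log scale.
#' @param link_strength slope tying a mediating metabolite's log-intensity
#'   to its source taxon's latent log-abundance.
#' @param seed integer seed; the study is a deterministic function of the
#'   configuration including the seed.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(n_subjects_per_group = 6,
                         groups = c("WT", "Tg", "TgR"),
                         timepoints = c(8, 9, 10),
                         n_taxa = 100,
                         n_metabolites = 300,
                         n_indicators = 11,
                         n_responsive_taxa = 5,
                         n_mediating_metabolites = 5,
                         disease_effect = 2.5,
                         reversal_fraction = 0.8,
                         library_size_mean = 20000,
                         library_size_dispersion = 0.3,
                         taxon_base_logmean_sd = 1,
                         metabolite_noise_sd = 0.3,
                         indicator_noise_sd = 0.3,
                         link_strength = 1,
                         seed = 1L) {
  cfg <- list(
    n_subjects_per_group = n_subjects_per_group, groups = groups,
    timepoints = timepoints, n_taxa = n_taxa,
    n_metabolites = n_metabolites, n_indicators = n_indicators,
    n_responsive_taxa = n_responsive_taxa,
    n_mediating_metabolites = n_mediating_metabolites,
    disease_effect = disease_effect, reversal_fraction = reversal_fraction,
    library_size_mean = library_size_mean,
    library_size_dispersion = library_size_dispersion,
    taxon_base_logmean_sd = taxon_base_logmean_sd,
    metabolite_noise_sd = metabolite_noise_sd,
    indicator_noise_sd = indicator_noise_sd,
    link_strength = link_strength, seed = as.integer(seed))
  validate_study_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_study_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid study configuration: '%s' %s", field, msg))
  }
  counts <- c("n_subjects_per_group", "n_taxa", "n_metabolites",
              "n_indicators")
  for (f in counts) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 1, f,
        "must be a count >= 1")
  }
  chk(cfg$n_responsive_taxa >= 0 && cfg$n_responsive_taxa <= cfg$n_taxa,
      "n_responsive_taxa", "must lie in [0, n_taxa]")
  chk(cfg$n_mediating_metabolites >= 0 &&
        cfg$n_mediating_metabolites <= cfg$n_metabolites,
      "n_mediating_metabolites", "must lie in [0, n_metabolites]")
  chk(cfg$n_mediating_metabolites == 0 || cfg$n_responsive_taxa >= 1,
      "n_mediating_metabolites",
      "requires n_responsive_taxa >= 1 (each mediator needs a source taxon)")
  chk(length(cfg$groups) == 3 && !anyDuplicated(cfg$groups), "groups",
      "must be three distinct labels (control, disease, treated)")
  chk(length(cfg$timepoints) >= 2 && !anyDuplicated(cfg$timepoints),
      "timepoints", "must be >= 2 distinct labels")
  chk(is.numeric(cfg$disease_effect) && cfg$disease_effect > 0,
      "disease_effect", "must be > 0")
  chk(cfg$reversal_fraction >= 0 && cfg$reversal_fraction <= 1,
      "reversal_fraction", "must lie in [0, 1]")
  chk(cfg$library_size_mean > 0, "library_size_mean", "must be > 0")
  chk(cfg$library_size_dispersion >= 0, "library_size_dispersion",
      "must be >= 0")
  invisible(cfg)
}

#' Generate a synthetic longitudinal multi-omics study
#'
#' Draws a complete study — taxon counts, metabolite intensities,
#' physiological indicators, sample metadata — from the generative model
#' described in [study_config()], together with ground-truth labels for the
#' planted responsive taxa, mediating metabolites and linked indicators.
#'
#' The model, deterministic given the seed: per-taxon baseline
#' log-abundances are Normal(0, `taxon_base_logmean_sd`); group/timepoint
#' effects multiply expected abundances of planted taxa as documented in
#' [study_config()]; expected abundances are closed to proportions and
#' counts drawn multinomially at a log-normal per-sample library size. Each
#' mediating metabolite's log-intensity is `link_strength` times its source
#' taxon's latent (pre-closure) log-abundance plus Gaussian noise;
#' unplanted metabolites are independent log-normals. Each linked indicator
#' is the exponential of a signed sum of its mediators' latent log-values
#' plus noise (exponentiated to keep indicator values positive; all
#' downstream association measures are rank-based or tested on both scales,
#' so the monotone transform is immaterial).
#'
#' @param config a [study_config()].
#' @return An object of class `mm_study`: a list with tibbles `abundance`
#'   (counts), `metabolites`, `indicators` (each samples x features with a
#'   `sample` id column), `metadata` (`sample`, `subject`, `group`,
#'   `timepoint`), and `truth` (see [summarize_truth()]).
#' @export
generate_study <- function(config) {
  if (!inherits(config, "study_config")) config <- do.call(study_config, config)
  validate_study_config(config)
  cfg <- config
  set.seed(substream_seed(cfg$seed, "generate_study"))

  n_g <- length(cfg$groups); n_t <- length(cfg$timepoints)
  n_s <- cfg$n_subjects_per_group
  meta <- tidyr::expand_grid(
    group = factor(cfg$groups, levels = cfg$groups),
    subj_idx = seq_len(n_s),
    timepoint = cfg$timepoints) |>
    mutate(subject = sprintf("%s_m%02d", .data$group, .data$subj_idx),
           sample = sprintf("%s_t%g", .data$subject, .data$timepoint)) |>
    select("sample", "subject", group = "group", timepoint = "timepoint") |>
    mutate(group = as.character(.data$group)) |>
    arrange(match(.data$group, cfg$groups), .data$subject, .data$timepoint)

  taxa <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
  mets <- sprintf("met_%03d", seq_len(cfg$n_metabolites))
  inds <- sprintf("ind_%02d", seq_len(cfg$n_indicators))

  ## planted structure
  resp_idx <- sort(sample.int(cfg$n_taxa, cfg$n_responsive_taxa))
  resp_dir <- if (cfg$n_responsive_taxa > 0)
    sample(c(-1, 1), cfg$n_responsive_taxa, replace = TRUE) else integer(0)
  med_idx <- sort(sample.int(cfg$n_metabolites, cfg$n_mediating_metabolites))
  # each mediator sources from one responsive taxon (round-robin) and links
  # to one indicator (round-robin over a random indicator subset)
  src_of_med <- if (cfg$n_mediating_metabolites > 0 && cfg$n_responsive_taxa > 0)
    resp_idx[((seq_len(cfg$n_mediating_metabolites) - 1) %% cfg$n_responsive_taxa) + 1]
  else integer(0)
  n_link <- min(cfg$n_mediating_metabolites, cfg$n_indicators)
  link_ind_pool <- if (n_link > 0) sort(sample.int(cfg$n_indicators, n_link)) else integer(0)
  ind_of_med <- if (cfg$n_mediating_metabolites > 0 && n_link > 0)
    link_ind_pool[((seq_len(cfg$n_mediating_metabolites) - 1) %% n_link) + 1]
  else integer(0)
  med_sign <- if (cfg$n_mediating_metabolites > 0)
    sample(c(-1, 1), cfg$n_mediating_metabolites, replace = TRUE) else integer(0)

  base_log <- rnorm(cfg$n_taxa, 0, cfg$taxon_base_logmean_sd)

  ## latent log-abundance per sample x taxon
  n_samp <- nrow(meta)
  lat <- matrix(rep(base_log, each = n_samp), nrow = n_samp,
                dimnames = list(meta$sample, taxa))
  t_index <- match(meta$timepoint, cfg$timepoints) - 1L
  log_eff <- log(cfg$disease_effect)
  for (k in seq_along(resp_idx)) {
    full <- resp_dir[k] * (t_index + 1) * log_eff
    scale_g <- dplyr::case_when(
      meta$group == cfg$groups[1] ~ 0,
      meta$group == cfg$groups[2] ~ 1,
      t_index == 0 ~ 1,                       # treated, pre-treatment
      TRUE ~ 1 - cfg$reversal_fraction)       # treated, post-treatment
    lat[, resp_idx[k]] <- lat[, resp_idx[k]] + full * scale_g
  }

  ## counts: close latent expectations, multinomial at log-normal depth
  props <- close_rows(exp(lat))
  libs <- round(rlnorm(n_samp, log(cfg$library_size_mean),
                       cfg$library_size_dispersion))
  libs <- pmax(libs, cfg$n_taxa)  # guard absurdly shallow draws
  counts <- t(vapply(seq_len(n_samp),
                     function(i) rmultinom(1, libs[i], props[i, ])[, 1],
                     numeric(cfg$n_taxa)))
  dimnames(counts) <- list(meta$sample, taxa)
  storage.mode(counts) <- "integer"

  ## metabolites
  met_log <- matrix(NA_real_, n_samp, cfg$n_metabolites,
                    dimnames = list(meta$sample, mets))
  null_met <- setdiff(seq_len(cfg$n_metabolites), med_idx)
  met_base <- rnorm(cfg$n_metabolites, 0, 1)
  for (j in null_met) {
    met_log[, j] <- met_base[j] + rnorm(n_samp, 0, cfg$metabolite_noise_sd)
  }
  for (k in seq_along(med_idx)) {
    j <- med_idx[k]
    met_log[, j] <- cfg$link_strength * lat[, src_of_med[k]] +
      rnorm(n_samp, 0, cfg$metabolite_noise_sd)
  }

  ## indicators
  ind_log <- matrix(NA_real_, n_samp, cfg$n_indicators,
                    dimnames = list(meta$sample, inds))
  ind_base <- rnorm(cfg$n_indicators, 0, 1)
  linked <- sort(unique(ind_of_med))
  for (j in seq_len(cfg$n_indicators)) {
    if (j %in% linked) {
      ks <- which(ind_of_med == j)
      contrib <- Reduce(`+`, lapply(ks, function(k) med_sign[k] * met_log[, med_idx[k]]))
      ind_log[, j] <- contrib + rnorm(n_samp, 0, cfg$indicator_noise_sd)
    } else {
      ind_log[, j] <- ind_base[j] + rnorm(n_samp, 0, cfg$indicator_noise_sd)
    }
  }

  truth <- list(
    responsive_taxa = tibble(taxon = taxa[resp_idx],
                             direction = as.integer(resp_dir)),
    mediating_metabolites = tibble(
      metabolite = mets[med_idx],
      source_taxon = taxa[src_of_med],
      indicator = inds[ind_of_med],
      sign = as.integer(med_sign)),
    linked_indicators = inds[linked])

  structure(list(
    abundance = matrix_to_tibble(counts),
    metabolites = matrix_to_tibble(exp(met_log)),
    indicators = matrix_to_tibble(exp(ind_log)),
    metadata = meta,
    truth = truth,
    config = cfg), class = "mm_study")
}

#' @export
print.mm_study <- function(x, ...) {
  cat(sprintf(
    "<mm_study> %d samples | %d taxa, %d metabolites, %d indicators\n",
    nrow(x$metadata), ncol(x$abundance) - 1L, ncol(x$metabolites) - 1L,
    ncol(x$indicators) - 1L))
  cat(sprintf("  groups: %s; timepoints: %s\n",
              paste(unique(x$metadata$group), collapse = "/"),
              paste(unique(x$metadata$timepoint), collapse = ", ")))
  cat(sprintf("  planted: %d responsive taxa, %d mediating metabolites\n",
              nrow(x$truth$responsive_taxa),
              nrow(x$truth$mediating_metabolites)))
  invisible(x)
}

#' Tabulate the planted ground truth of a synthetic study
#'
#' @param study an `mm_study` from [generate_study()].
#' @return A tibble with one row per planted feature: `feature`, `layer`
#'   (taxon / metabolite / indicator), `role`, and `direction` (planted
#'   effect direction; `NA` for indicators, whose sign depends on their
#'   mediators).
#' @export
summarize_truth <- function(study) {
  if (is.null(study$truth)) abort("study carries no truth labels")
  tr <- study$truth
  bind_rows(
    tibble(feature = tr$responsive_taxa$taxon, layer = "taxon",
           role = "responsive", direction = tr$responsive_taxa$direction),
    tibble(feature = tr$mediating_metabolites$metabolite,
           layer = "metabolite", role = "mediating",
           direction = tr$mediating_metabolites$sign),
    tibble(feature = tr$linked_indicators, layer = "indicator",
           role = "linked", direction = NA_integer_))
}
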