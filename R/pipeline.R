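#' Pipeline configuration
#'
#' Bundles a study source (a [study_config()] simulate block, or paths to
#' on-disk tables) with every stage parameter. Defaults are the
#' conventional values of the workflow: prevalence filter 120/12, taxon
#' VIP cut 0.7, metabolite VIP cut 1.0 with p < 0.05, candidate tails
#' 1000/1000, 1000 permutation iterations, q < 0.05.
#'
#' @param simulate a [study_config()] (or argument list for one); mutually
#'   exclusive with `paths`.
#' @param paths named list with `abundance`, `metabolites`, `indicators`,
#'   `metadata` (TSV paths) and optionally `truth`.
#' @param groups length-3 character: control, disease, treated.
#' @param filter_min_sum,filter_min_occurrence taxon prevalence filter.
#' @param taxon_vip,metabolite_vip,metabolite_p screen thresholds.
#' @param n_components PLS-DA components per screen.
#' @param top_n,bottom_n,iterations,q_threshold,min_support,renormalize
#'   ensemble network parameters.
#' @param seed global seed; all stage randomness derives from it through
#'   named substreams.
#' @param out_dir output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            groups = c("WT", "Tg", "TgR"),
                            filter_min_sum = 120,
                            filter_min_occurrence = 12,
                            taxon_vip = 0.7, metabolite_vip = 1.0,
                            metabolite_p = 0.05, n_components = 2,
                            top_n = 1000, bottom_n = 1000,
                            iterations = 1000, q_threshold = 0.05,
                            min_support = 2, renormalize = TRUE,
                            seed = 1L, out_dir = tempfile("microrev_run_")) {
  if (is.null(simulate) && is.null(paths)) {
    abort("pipeline config needs either a simulate block or input paths")
  }
  if (!is.null(paths)) {
    need <- c("abundance", "metabolites", "indicators", "metadata")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0) {
      abort(sprintf("paths lacks: %s", paste(miss, collapse = ", ")))
    }
    gone <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(gone) > 0) {
      abort(sprintf("input path(s) do not exist: %s",
                    paste(gone, collapse = ", ")))
    }
  }
  if (!is.null(simulate) && !inherits(simulate, "study_config")) {
    simulate <- do.call(study_config, simulate)
  }
  stopifnot(taxon_vip >= 0, metabolite_vip >= 0,
            metabolite_p > 0, metabolite_p <= 1,
            q_threshold > 0, q_threshold <= 1, iterations >= 100,
            min_support >= 1, length(groups) == 3)
  structure(list(
    simulate = simulate, paths = paths, groups = groups,
    filter_min_sum = filter_min_sum,
    filter_min_occurrence = filter_min_occurrence,
    taxon_vip = taxon_vip, metabolite_vip = metabolite_vip,
    metabolite_p = metabolite_p, n_components = n_components,
    top_n = top_n, bottom_n = bottom_n, iterations = iterations,
    q_threshold = q_threshold, min_support = min_support,
    renormalize = renormalize, seed = as.integer(seed),
    out_dir = out_dir), class = "pipeline_config")
}

#' Run the full drug-response discovery pipeline
#'
#' Fixed stage order: simulate (or load) -> filter -> diversity ->
#' per-timepoint control-vs-disease screens (taxa and metabolites) ->
#' trend consistency -> treatment-reversal filter -> qPCR-style validation
#' of trend-consistent taxa -> ensemble co-occurrence network ->
#' tripartite network (trend-consistent taxa x reversed metabolites x
#' indicators) -> bridge-metabolite ranking. Every stage output is written
#' under `config$out_dir` and checksummed into `manifest.json`; identical
#' config + seed reproduce identical checksums. When ground truth is
#' available a recovery report (precision/recall of planted features) is
#' added.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  cat("", file = log_path)
  stage_times <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    dt <- proc.time()[["elapsed"]] - t0
    stage_times[[name]] <<- dt
    cat(sprintf("[%s] %.2fs\n", name, dt), file = log_path, append = TRUE)
    res
  }

  ## stage: simulate / load
  study <- timed("input", {
    if (!is.null(cfg$simulate)) {
      st <- generate_study(cfg$simulate)
      write_study(st, file.path(cfg$out_dir, "study"))
      st
    } else {
      ab <- read_abundance_table(cfg$paths$abundance, cfg$paths$metadata)
      list(abundance = ab$abundance,
           metabolites = read_feature_table(cfg$paths$metabolites),
           indicators = read_feature_table(cfg$paths$indicators),
           metadata = ab$metadata,
           truth = if (!is.null(cfg$paths$truth)) read_truth(cfg$paths$truth))
    }
  })
  meta <- study$metadata
  grp <- cfg$groups
  tps <- sort(unique(meta$timepoint))

  ## stage: filter
  filtered <- timed("filter", filter_features(
    study$abundance, meta, min_sum = cfg$filter_min_sum,
    min_occurrence = cfg$filter_min_occurrence))
  write_feature_table(filtered, file.path(cfg$out_dir, "abundance_filtered.tsv"))

  ## stage: diversity
  diversity <- timed("diversity", {
    alpha <- alpha_diversity(filtered)
    d <- beta_diversity(filtered, "bray")
    ord <- pcoa(d, n_axes = 2)
    readr::write_tsv(alpha, file.path(cfg$out_dir, "alpha_diversity.tsv"),
                     progress = FALSE)
    readr::write_tsv(ord$coordinates, file.path(cfg$out_dir, "pcoa.tsv"),
                     progress = FALSE)
    list(alpha = alpha, distance = d, ordination = ord)
  })

  ## stage: screens (control vs disease, per timepoint, both layers)
  rel_ab <- matrix_to_tibble(close_rows(feature_matrix(filtered)))
  met_norm <- total_ion_normalize(study$metabolites)
  screens <- timed("screen", {
    per_tp <- function(tbl, vip_cut, p_cut) {
      setNames(lapply(tps, function(tp) {
        keep <- meta$sample[meta$timepoint == tp]
        differential_screen(filter(tbl, .data$sample %in% keep),
                            meta, groups = grp[1:2],
                            vip_threshold = vip_cut, p_threshold = p_cut,
                            n_components = cfg$n_components)
      }), as.character(tps))
    }
    list(taxa = per_tp(rel_ab, cfg$taxon_vip, NULL),
         metabolites = per_tp(met_norm, cfg$metabolite_vip,
                              cfg$metabolite_p))
  })
  for (layer in names(screens)) {
    for (tp in names(screens[[layer]])) {
      readr::write_tsv(screens[[layer]][[tp]],
                       file.path(cfg$out_dir,
                                 sprintf("screen_%s_t%s.tsv", layer, tp)),
                       progress = FALSE)
    }
  }

  ## stage: trends
  trends <- timed("trends", list(
    taxa = trend_consistency(screens$taxa),
    metabolites = trend_consistency(screens$metabolites)))
  readr::write_tsv(trends$taxa, file.path(cfg$out_dir, "trends_taxa.tsv"),
                   progress = FALSE)
  readr::write_tsv(trends$metabolites,
                   file.path(cfg$out_dir, "trends_metabolites.tsv"),
                   progress = FALSE)
  consistent_taxa <- trends$taxa$feature[trends$taxa$consistent]
  consistent_mets <- trends$metabolites$feature[trends$metabolites$consistent]

  ## stage: reversal (metabolites; treatment acts after the first timepoint)
  reversal <- timed("reversal", {
    if (length(consistent_mets) == 0) {
      tibble(feature = character(0), reversed = logical(0))
    } else {
      reversal_screen(met_norm, meta, consistent_mets, groups = grp,
                      treatment_timepoints = tps[-1])
    }
  })
  readr::write_tsv(reversal, file.path(cfg$out_dir, "reversal_metabolites.tsv"),
                   progress = FALSE)
  reversed_mets <- reversal$feature[reversal$reversed]

  ## stage: qPCR-style absolute-quantification validation of candidate taxa.
  ## Synthetic Ct values are derived from the counts through a simulated
  ## dilution-series standard curve (seeded substream) — a synthetic
  ## stand-in for a wet-lab assay, exercising the same quantification path.
  qpcr <- timed("qpcr", {
    if (length(consistent_taxa) == 0) {
      list(curve = NULL,
           validation = tibble(taxon = character(0), p = numeric(0),
                               direction = character(0),
                               responsive = logical(0)))
    } else {
      set.seed(substream_seed(cfg$seed, "qpcr"))
      dil <- rep(2:7, each = 2)
      curve <- fit_standard_curve(dil, 38 - 3.32193 * dil + rnorm(12, 0, 0.1))
      last_tp <- max(tps)
      sel <- meta$timepoint == last_tp
      cm <- feature_matrix(filtered)[meta$sample[sel], consistent_taxa,
                                     drop = FALSE]
      ct <- curve$intercept + curve$slope * log10(pmax(cm, 0.5)) +
        matrix(rnorm(length(cm), 0, 0.1), nrow(cm))
      copies <- quantify_copies(ct, curve)
      long <- matrix_to_tibble(copies) |>
        tidyr::pivot_longer(-"sample", names_to = "taxon",
                            values_to = "copies") |>
        left_join(meta[c("sample", "group")], by = "sample")
      list(curve = curve,
           validation = validate_responsive(long, groups = grp))
    }
  })
  readr::write_tsv(qpcr$validation, file.path(cfg$out_dir, "qpcr_validation.tsv"),
                   progress = FALSE)

  ## stage: ensemble co-occurrence network over taxa
  network <- timed("conet", conet(
    study$abundance, meta, top_n = cfg$top_n, bottom_n = cfg$bottom_n,
    iterations = cfg$iterations, q_threshold = cfg$q_threshold,
    min_support = cfg$min_support, min_sum = cfg$filter_min_sum,
    min_occurrence = cfg$filter_min_occurrence,
    renormalize = cfg$renormalize,
    seed = substream_seed(cfg$seed, "conet")))
  write_network(network, file.path(cfg$out_dir, "conet_edges.tsv"), "edge_tsv")
  write_network(network, file.path(cfg$out_dir, "conet.graphml"), "graphml")

  ## stage: tripartite network and bridge ranking
  tripartite <- timed("tripartite", {
    taxa_layer <- if (length(consistent_taxa) > 0)
      rel_ab[c("sample", consistent_taxa)] else rel_ab["sample"]
    met_layer <- if (length(reversed_mets) > 0)
      met_norm[c("sample", reversed_mets)] else met_norm["sample"]
    if (ncol(taxa_layer) > 1 && ncol(met_layer) > 1) {
      tripartite_network(taxa_layer, met_layer, study$indicators,
                         q_threshold = cfg$q_threshold)
    } else NULL
  })
  bridges <- timed("bridges", {
    if (is.null(tripartite)) {
      tibble(metabolite = character(0), degree = integer(0),
             taxon_degree = integer(0), indicator_degree = integer(0),
             sum_abs_rho = numeric(0), rank = integer(0))
    } else rank_bridge_metabolites(tripartite)
  })
  if (!is.null(tripartite)) {
    write_network(tripartite, file.path(cfg$out_dir, "tripartite_edges.tsv"),
                  "edge_tsv")
  }
  readr::write_tsv(bridges, file.path(cfg$out_dir, "bridge_ranking.tsv"),
                   progress = FALSE)

  ## recovery report against ground truth, when present
  recovery <- NULL
  if (!is.null(study$truth)) {
    tr <- study$truth
    planted_taxa <- tr$responsive_taxa$taxon
    planted_mets <- tr$mediating_metabolites$metabolite
    top10 <- head(bridges$metabolite, 10)
    recovery <- list(
      taxa_trend_recall = if (length(planted_taxa) > 0)
        mean(planted_taxa %in% consistent_taxa) else NA,
      taxa_trend_false = length(setdiff(consistent_taxa, planted_taxa)),
      metabolite_reversed_recall = if (length(planted_mets) > 0)
        mean(planted_mets %in% reversed_mets) else NA,
      bridge_top10_recall = if (length(planted_mets) > 0)
        mean(planted_mets %in% top10) else NA,
      bridge_top10_false = length(setdiff(top10, planted_mets)))
    jsonlite::write_json(recovery, file.path(cfg$out_dir, "recovery.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  ## manifest: config snapshot + per-output checksums (deterministic;
  ## wall-clock timings live in run.log, not here)
  outputs <- sort(setdiff(list.files(cfg$out_dir, recursive = TRUE),
                          c("run.log", "manifest.json")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("microrev")),
    seed = cfg$seed,
    config = config_snapshot(cfg),
    checksums = as.list(tools::md5sum(file.path(cfg$out_dir, outputs)) |>
                          setNames(outputs)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    study = study, filtered = filtered, diversity = diversity,
    screens = screens, trends = trends, reversal = reversal, qpcr = qpcr,
    network = network, tripartite = tripartite, bridges = bridges,
    recovery = recovery, manifest = manifest,
    stage_seconds = stage_times, out_dir = cfg$out_dir))
}

config_snapshot <- function(cfg) {
  snap <- unclass(cfg)
  snap$out_dir <- NULL                       # path varies across hosts
  if (!is.null(snap$simulate)) snap$simulate <- unclass(snap$simulate)
  snap
}
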