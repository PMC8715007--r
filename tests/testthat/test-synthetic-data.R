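test_that("study generation is deterministic and dimensionally correct", {
  s1 <- generate_study(small_config(seed = 3))
  s2 <- generate_study(small_config(seed = 3))
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$metabolites, s2$metabolites)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(small_config(seed = 4))
  expect_false(identical(s1$abundance, s3$abundance))

  # 3 groups x 3 timepoints x 6 subjects
  expect_equal(nrow(s1$metadata), 54)
  expect_equal(nrow(s1$abundance), 54)
  expect_equal(nrow(s1$metabolites), 54)
  expect_equal(nrow(s1$indicators), 54)
  expect_setequal(s1$abundance$sample, s1$metadata$sample)
  expect_setequal(s1$metabolites$sample, s1$metadata$sample)
  # one (subject, timepoint) assignment per sample
  expect_false(anyDuplicated(s1$metadata[c("subject", "timepoint")]) > 0)
})

test_that("counts are nonnegative integers and metabolites positive", {
  st <- generate_study(small_config(seed = 8))
  m <- microrev:::feature_matrix(st$abundance)
  expect_true(all(m >= 0))
  expect_true(all(m == floor(m)))
  expect_true(all(microrev:::feature_matrix(st$metabolites) > 0))
  expect_true(all(microrev:::feature_matrix(st$indicators) > 0))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(study_config(n_taxa = 0), "n_taxa")
  expect_error(study_config(disease_effect = -1), "disease_effect")
  expect_error(study_config(reversal_fraction = 1.5), "reversal_fraction")
  expect_error(study_config(n_responsive_taxa = 200), "n_responsive_taxa")
  expect_error(study_config(n_responsive_taxa = 0,
                            n_mediating_metabolites = 3),
               "n_mediating_metabolites")
})

test_that("planted disease-up taxa rise monotonically in relative abundance", {
  # no baseline spread, large library: observed proportions track the
  # latent expectation closely
  st <- generate_study(study_config(
    n_taxa = 20, n_metabolites = 10, n_indicators = 3,
    n_responsive_taxa = 2, n_mediating_metabolites = 2,
    taxon_base_logmean_sd = 0, library_size_mean = 2e5,
    library_size_dispersion = 0, disease_effect = 2.5, seed = 5))
  rel <- microrev:::close_rows(microrev:::feature_matrix(st$abundance))
  meta <- st$metadata
  up <- st$truth$responsive_taxa$taxon[st$truth$responsive_taxa$direction == 1]
  skip_if(length(up) == 0)
  for (tx in up) {
    means <- sapply(sort(unique(meta$timepoint)), function(tp) {
      mean(rel[meta$group == "Tg" & meta$timepoint == tp, tx])
    })
    expect_true(all(diff(means) > 0))
  }
})

test_that("multinomial closure: per-sample counts sum to the drawn library", {
  st <- generate_study(small_config(seed = 2))
  lib <- rowSums(microrev:::feature_matrix(st$abundance))
  # library sizes are log-normal around the configured mean
  expect_true(all(lib > 0))
  expect_gt(mean(lib), 2000)
  expect_lt(mean(lib), 12000)
})

test_that("null study gives calibrated Wilcoxon rejection on taxa", {
  st <- generate_study(study_config(
    n_taxa = 1000, n_responsive_taxa = 0, n_mediating_metabolites = 0,
    disease_effect = 1, seed = 5))
  meta <- st$metadata
  keep <- meta$sample[meta$timepoint == 9]
  rel <- study_rel_abundance(st)
  scr <- differential_screen(dplyr::filter(rel, sample %in% keep), meta,
                             c("WT", "Tg"), vip_threshold = 0,
                             p_threshold = NULL)
  expect_gt(mean(scr$p < 0.05), 0.03)
  expect_lt(mean(scr$p < 0.05), 0.07)
})

test_that("mediating metabolites track their source taxon (link recovery)", {
  hits <- sapply(1:10, function(s) {
    st <- generate_study(small_config(seed = s, link_strength = 1.5,
                                      metabolite_noise_sd = 0.2))
    rel <- microrev:::close_rows(microrev:::feature_matrix(st$abundance))
    links <- st$truth$mediating_metabolites
    met <- microrev:::feature_matrix(st$metabolites)
    rho <- mapply(function(m_id, t_id) {
      cor(met[, m_id], rel[rownames(met), t_id], method = "spearman")
    }, links$metabolite, links$source_taxon)
    mean(rho > 0)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("summarize_truth tabulates every planted feature once", {
  st <- generate_study(study_config(
    n_taxa = 30, n_metabolites = 40, n_indicators = 4,
    n_responsive_taxa = 5, n_mediating_metabolites = 5, seed = 1))
  tt <- summarize_truth(st)
  n_linked <- length(st$truth$linked_indicators)
  expect_equal(nrow(tt), 5 + 5 + n_linked)
  expect_setequal(unique(tt$layer), c("taxon", "metabolite", "indicator"))

  st0 <- generate_study(study_config(
    n_taxa = 10, n_metabolites = 10, n_indicators = 2,
    n_responsive_taxa = 0, n_mediating_metabolites = 0, seed = 1))
  expect_equal(nrow(summarize_truth(st0)), 0)
  st0$truth <- NULL
  expect_error(summarize_truth(st0), "truth")
})

test_that("truth labels round-trip through write/read unchanged", {
  st <- generate_study(small_config(seed = 6))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr$responsive_taxa, st$truth$responsive_taxa)
  expect_equal(tr$mediating_metabolites, st$truth$mediating_metabolites)
  expect_equal(tr$linked_indicators, st$truth$linked_indicators)
  cfg <- read_study_config(file.path(dir, "config.json"))
  expect_equal(cfg$seed, st$config$seed)
  expect_equal(cfg$n_taxa, st$config$n_taxa)
})
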