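test_that("prevalence filter keeps taxa passing both clauses in a condition", {
  m <- matrix(0L, 20, 3, dimnames = list(sprintf("s%02d", 1:20),
                                         c("t1", "t2", "t3")))
  m[1:15, "t1"] <- 14L   # sum 210, occ 15 -> keep
  m[1:15, "t2"] <- 6L    # sum  90, occ 15 -> drop (sum below)
  m[1:5, "t3"] <- 40L    # sum 200, occ  5 -> drop (occurrence below)
  tbl <- wide_tbl(m)
  out <- filter_features(tbl, rep("c1", 20), min_sum = 120,
                         min_occurrence = 12)
  expect_equal(setdiff(names(out), "sample"), "t1")
  expect_setequal(attr(out, "discarded"), c("t2", "t3"))

  # zero thresholds: identity
  all_kept <- filter_features(tbl, rep("c1", 20), min_sum = 0,
                              min_occurrence = 0)
  expect_equal(names(all_kept), names(tbl))

  # all-zero taxon always discarded (fails occurrence in every condition)
  m2 <- cbind(m, t4 = 0L)
  out2 <- filter_features(wide_tbl(m2), rep("c1", 20), min_sum = 0,
                          min_occurrence = 1)
  expect_false("t4" %in% names(out2))
})

test_that("filter is per-condition: passing in one condition suffices", {
  m <- matrix(0L, 24, 1, dimnames = list(sprintf("s%02d", 1:24), "t1"))
  m[1:12, 1] <- 15L   # condition A: sum 180, occ 12
  tbl <- wide_tbl(m)
  cond <- rep(c("A", "B"), each = 12)
  out <- filter_features(tbl, cond, min_sum = 120, min_occurrence = 12)
  expect_true("t1" %in% names(out))
  expect_error(filter_features(tbl, factor(cond, levels = c("A", "B", "C")),
                               min_sum = 0, min_occurrence = 0), "empty")
})

test_that("total ion normalisation closes rows and is idempotent", {
  tbl <- wide_tbl(matrix(c(2, 2, 4, 1, 1, 2), 2, 3, byrow = TRUE,
                         dimnames = list(c("a", "b"), c("f1", "f2", "f3"))))
  out <- total_ion_normalize(tbl)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(0.25, 0.25, 0.5))
  expect_equal(total_ion_normalize(out), out)
  set.seed(31)
  r <- wide_tbl(matrix(runif(50, 0.1, 5), 5, 10,
                       dimnames = list(paste0("s", 1:5), paste0("f", 1:10))))
  rn <- microrev:::feature_matrix(total_ion_normalize(r))
  expect_true(all(abs(rowSums(rn) - 1) < 1e-12))
  bad <- wide_tbl(matrix(0, 1, 2, dimnames = list("z", c("f1", "f2"))))
  expect_error(total_ion_normalize(bad), "z")
})

test_that("differential screen finds overwhelming planted effects", {
  st <- generate_study(study_config(
    n_taxa = 30, n_metabolites = 20, n_indicators = 3,
    n_responsive_taxa = 2, n_mediating_metabolites = 2,
    disease_effect = 4, seed = 17))
  meta <- st$metadata
  keep <- meta$sample[meta$timepoint == 10]
  rel <- study_rel_abundance(st)
  scr <- differential_screen(dplyr::filter(rel, sample %in% keep), meta,
                             c("WT", "Tg"), vip_threshold = 1,
                             p_threshold = 0.05)
  planted <- st$truth$responsive_taxa
  for (i in seq_len(nrow(planted))) {
    row <- scr[scr$feature == planted$taxon[i], ]
    expect_true(row$selected)
    expect_equal(row$direction, planted$direction[i])
  }
  expect_true(all(scr$q >= scr$p))
  expect_true(all(scr$vip >= 0))
})

test_that("identical group distributions give p = 1 and no selection", {
  m <- matrix(rlnorm(60), 12, 5,
              dimnames = list(sprintf("s%02d", 1:12), paste0("f", 1:5)))
  m[7:12, ] <- m[1:6, ]   # disease group duplicates control exactly
  meta <- tibble::tibble(sample = rownames(m),
                         group = rep(c("WT", "Tg"), each = 6))
  scr <- differential_screen(wide_tbl(m), meta, c("WT", "Tg"),
                             vip_threshold = 0.7, p_threshold = 0.05)
  expect_true(all(scr$p == 1))
  expect_false(any(scr$selected))
  expect_true(all(scr$direction == 0))
})

test_that("vip_threshold = 0 with no p cut selects everything; selection is monotone", {
  st <- generate_study(small_config(seed = 18))
  meta <- st$metadata
  keep <- meta$sample[meta$timepoint == 9]
  rel <- dplyr::filter(study_rel_abundance(st), sample %in% keep)
  all_sel <- differential_screen(rel, meta, c("WT", "Tg"),
                                 vip_threshold = 0, p_threshold = NULL)
  expect_true(all(all_sel$selected))
  hi <- differential_screen(rel, meta, c("WT", "Tg"),
                            vip_threshold = 1.2, p_threshold = NULL)
  lo <- differential_screen(rel, meta, c("WT", "Tg"),
                            vip_threshold = 0.6, p_threshold = NULL)
  expect_true(all(hi$feature[hi$selected] %in% lo$feature[lo$selected]))
  expect_error(differential_screen(rel, meta, c("WT", "Tg", "TgR")),
               "two groups")
})

test_that("trend consistency requires selection and one direction throughout", {
  mk <- function(sel, dir) tibble::tibble(
    feature = c("f1", "f2", "f3", "f4"), vip = 1, p = 0.01, q = 0.01,
    direction = dir, selected = sel)
  screens <- list(
    `8` = mk(c(TRUE, TRUE, TRUE, TRUE), c(1L, 1L, 1L, 0L)),
    `9` = mk(c(TRUE, TRUE, FALSE, TRUE), c(1L, 1L, 1L, 0L)),
    `10` = mk(c(TRUE, TRUE, TRUE, TRUE), c(1L, -1L, 1L, 0L)))
  tr <- trend_consistency(screens)
  expect_true(tr$consistent[tr$feature == "f1"])       # all selected, all +1
  expect_false(tr$consistent[tr$feature == "f2"])      # (+1,+1,-1)
  expect_false(tr$consistent[tr$feature == "f3"])      # selected 2 of 3
  expect_false(tr$consistent[tr$feature == "f4"])      # direction 0
  expect_equal(tr$overall_direction[tr$feature == "f1"], 1L)
  expect_equal(tr$overall_direction[tr$feature == "f2"], 0L)

  # a feature absent from one timepoint counts as unselected there
  screens2 <- screens
  screens2$`9` <- screens2$`9`[screens2$`9`$feature != "f1", ]
  tr2 <- trend_consistency(screens2)
  expect_false(tr2$consistent[tr2$feature == "f1"])
  expect_error(trend_consistency(screens["8"]), "2 timepoints")
})

test_that("reversal requires strict shrinkage toward control at every timepoint", {
  mk_data <- function(treated_vals) {
    meta <- tidyr::expand_grid(group = c("WT", "Tg", "TgR"),
                               rep = 1:4, timepoint = c(9, 10)) |>
      dplyr::mutate(sample = sprintf("%s_%d_t%d", group, rep, timepoint),
                    subject = sprintf("%s_%d", group, rep))
    vals <- dplyr::case_when(meta$group == "WT" ~ 1,
                             meta$group == "Tg" ~ 5,
                             TRUE ~ treated_vals)
    tbl <- tibble::tibble(sample = meta$sample, f1 = vals + 0.001 * seq_len(nrow(meta)))
    list(tbl = tbl, meta = meta)
  }
  d <- mk_data(2)   # treated median 2: |2-1| < |5-1| at both timepoints
  out <- reversal_screen(d$tbl, d$meta, "f1",
                         treatment_timepoints = c(9, 10))
  expect_true(out$reversed)
  expect_true(all(out$shrinkage_9 < 1, out$shrinkage_10 < 1))

  d2 <- mk_data(5)  # treated == disease -> not reversed
  expect_false(reversal_screen(d2$tbl, d2$meta, "f1",
                               treatment_timepoints = c(9, 10))$reversed)

  # reversed at one timepoint only -> not reversed
  d3 <- mk_data(2)
  idx <- d3$meta$group == "TgR" & d3$meta$timepoint == 10
  d3$tbl$f1[idx] <- 7
  expect_false(reversal_screen(d3$tbl, d3$meta, "f1",
                               treatment_timepoints = c(9, 10))$reversed)

  # missing group at a timepoint errors
  d4 <- mk_data(2)
  keep <- !(d4$meta$group == "TgR" & d4$meta$timepoint == 10)
  expect_error(reversal_screen(d4$tbl[keep, ], d4$meta[keep, ], "f1",
                               treatment_timepoints = c(9, 10)), "10")
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "finite")
})

test_that("bh_adjust equals the brute-force double loop on random vectors", {
  set.seed(33)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  # q >= p elementwise and monotone in sorted order
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("wilcoxon type-I error is calibrated at n = 6 vs 6", {
  st <- generate_study(study_config(
    n_metabolites = 2000, n_responsive_taxa = 1,
    n_mediating_metabolites = 0, disease_effect = 1, seed = 11))
  meta <- st$metadata
  keep <- meta$sample[meta$timepoint == 9]
  mn <- total_ion_normalize(st$metabolites)
  scr <- differential_screen(dplyr::filter(mn, sample %in% keep), meta,
                             c("WT", "Tg"), vip_threshold = 0,
                             p_threshold = NULL)
  for (a in c(0.01, 0.05, 0.1)) {
    rej <- mean(scr$p < a)
    expect_gt(rej, a - 0.02)
    expect_lt(rej, a + 0.02)
  }
})
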