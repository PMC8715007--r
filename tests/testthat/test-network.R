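mk_profiles <- function(n = 20, n_feat = 10, seed = 41) {
  set.seed(seed)
  m <- matrix(rlnorm(n * n_feat), n, n_feat,
              dimnames = list(sprintf("s%02d", 1:n),
                              sprintf("f%02d", 1:n_feat)))
  m / rowSums(m)
}

test_that("pairwise scores satisfy identity and scale invariance", {
  m <- mk_profiles()
  pe <- pairwise_scores(m, "pearson")
  br <- pairwise_scores(m, "bray")
  kl <- pairwise_scores(m, "kld")
  expect_true(all(abs(diag(pe) - 1) < 1e-12))
  expect_true(all(diag(br) == 0))
  expect_true(all(diag(kl) == 0))
  expect_equal(pe, t(pe)); expect_equal(br, t(br)); expect_equal(kl, t(kl))
  expect_true(all(pe >= -1 - 1e-12 & pe <= 1 + 1e-12))
  expect_true(all(br >= 0 & br <= 1))
  expect_true(all(kl >= 0))

  # proportional profiles have zero Bray after per-profile closure
  m2 <- m
  m2[, 2] <- 3 * m2[, 1]
  m2 <- m2 / rowSums(m2)
  br2 <- pairwise_scores(m2, "bray")
  expect_lt(br2[1, 2], 1e-12)
  expect_error(pairwise_scores(m[1:3, ], "pearson"), "4 samples")
})

test_that("symmetrised KL matches direct formula evaluation", {
  # two-point profiles evaluated through the same kernel the null uses
  x <- c(0.5, 0.5); y <- c(0.9, 0.1)
  perm_id <- matrix(1:2, ncol = 1)
  got <- microrev:::cpp_perm_null(x, y, perm_id, 4L, FALSE)
  z <- 1 + 2 * 1e-6
  p <- (x + 1e-6) / z; q <- (y + 1e-6) / z
  oracle <- 0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
  expect_equal(as.numeric(got), oracle, tolerance = 1e-12)
  # against hand arithmetic without pseudocount (which only perturbs ~1e-5)
  hand <- 0.5 * (0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1) +
                   0.9 * log(0.9 / 0.5) + 0.1 * log(0.1 / 0.5))
  expect_equal(as.numeric(got), hand, tolerance = 1e-4)
})

test_that("constant profiles are skipped for correlation measures", {
  m <- mk_profiles(n_feat = 5)
  m[, 3] <- 0.1                      # constant share of every sample
  m[, -3] <- m[, -3] * 0.9 / rowSums(m[, -3])
  s <- pairwise_scores(m, "pearson")
  expect_true(all(is.na(s[3, ])))
  expect_true("f03" %in% attr(s, "skipped"))
})

test_that("candidate selection counts and tails are exact", {
  m <- mk_profiles(n = 20, n_feat = 30, seed = 42)
  s <- pairwise_scores(m, "pearson")
  cand <- select_candidates(s, top_n = 1000, bottom_n = 1000)
  expect_equal(nrow(cand), 2 * choose(30, 2))   # 435 + 435: saturation
  expect_equal(sum(cand$tail == "top"), 435)

  top1 <- select_candidates(s, top_n = 1, bottom_n = 0)
  ut <- upper.tri(s)
  expect_equal(top1$score, max(s[ut]))
  expect_equal(top1$sign, 1L)

  # dissimilarity orientation: small bray = co-presence
  sb <- pairwise_scores(m, "bray")
  cb <- select_candidates(sb, top_n = 1, bottom_n = 1)
  expect_equal(cb$sign[cb$tail == "bottom"], 1L)
  expect_equal(cb$sign[cb$tail == "top"], -1L)
})

test_that("100 features yield exactly 1000 + 1000 candidates per measure", {
  m <- mk_profiles(n = 20, n_feat = 100, seed = 43)
  for (me in c("pearson", "bray")) {
    cand <- select_candidates(pairwise_scores(m, me))
    expect_equal(sum(cand$tail == "top"), 1000)
    expect_equal(sum(cand$tail == "bottom"), 1000)
  }
})

test_that("permutation p attains its floor on perfect correlation", {
  set.seed(44)
  x <- rlnorm(20)
  m <- cbind(a = x, b = 2 * x, c = rlnorm(20), d = rlnorm(20))
  m <- m / rowSums(m)
  obs <- cor(m[, "a"], m[, "b"])
  cand <- tibble::tibble(source = "a", target = "b", measure = "pearson",
                         score = obs, sign = 1L, tail = "top")
  es <- edge_significance(m, cand, iterations = 1000, renormalize = FALSE,
                          seed = 7)
  expect_equal(es$p, 1 / 1001, tolerance = 1e-12)
  # determinism given the seed
  es2 <- edge_significance(m, cand, iterations = 1000, renormalize = FALSE,
                           seed = 7)
  expect_identical(es$p, es2$p)
  expect_identical(es$boot_lo, es2$boot_lo)
  expect_error(edge_significance(m, cand, iterations = 50), "100")
})

test_that("permutation p is rank-invariant under spearman", {
  m <- mk_profiles(n = 16, n_feat = 6, seed = 45)
  # order-preserving transform of one feature, filler column keeps rows
  # closed so the ranks the test sees are exactly the transformed ones
  m2 <- m
  m2[, 1] <- m2[, 1]^2 / 2
  m2[, 6] <- m2[, 6] + (m[, 1] - m2[, 1])
  cand <- function(mm) tibble::tibble(
    source = "f01", target = "f02", measure = "spearman",
    score = cor(mm[, 1], mm[, 2], method = "spearman"),
    sign = 1L, tail = "top")
  p1 <- edge_significance(m, cand(m), iterations = 500,
                          renormalize = FALSE, seed = 9)$p
  p2 <- edge_significance(m2, cand(m2), iterations = 500,
                          renormalize = FALSE, seed = 9)$p
  expect_identical(p1, p2)
})

test_that("edge consolidation merges by support and sign agreement", {
  base <- tibble::tibble(
    source = c("a", "a", "b", "b", "c"),
    target = c("b", "b", "c", "c", "d"),
    measure = c("pearson", "spearman", "pearson", "spearman", "pearson"),
    score = c(0.9, 0.88, 0.8, -0.8, 0.7),
    sign = c(1L, 1L, 1L, -1L, 1L),
    tail = "top",
    p = c(0.001, 0.002, 0.001, 0.001, 0.003))
  out <- consolidate_edges(base, q_threshold = 0.05, min_support = 2)
  expect_equal(nrow(out), 1)             # a-b retained, b-c sign conflict
  expect_equal(out$support, 2)
  expect_equal(out$sign, 1L)
  expect_equal(nrow(attr(out, "dropped")), 1)
  # Fisher combination of the supporting p values
  expect_equal(out$combined_p,
               pchisq(-2 * (log(0.001) + log(0.002)), df = 4,
                      lower.tail = FALSE))

  one <- consolidate_edges(base, min_support = 1)
  expect_true("c" %in% one$source)       # single-measure survivor kept
  expect_equal(nrow(consolidate_edges(base[0, ])), 0)
})

test_that("renormalized null suppresses compositional exclusion artifacts", {
  count_excl <- function(renorm, seed) {
    set.seed(seed)
    n <- 30; n_feat <- 40
    raw <- matrix(rlnorm(n * n_feat, 0, 0.5), n, n_feat)
    raw[, 1] <- raw[, 1] * 50          # dominant taxon
    m <- raw / rowSums(raw)
    colnames(m) <- sprintf("f%02d", 1:n_feat)
    cand <- select_candidates(pairwise_scores(m, "pearson"),
                              top_n = 200, bottom_n = 200)
    es <- edge_significance(m, cand, iterations = 500,
                            renormalize = renorm, seed = seed)
    es$q <- bh_adjust(es$p)
    sum(es$q < 0.05 & es$sign == -1)
  }
  naive <- sapply(1:10, function(s) count_excl(FALSE, s))
  renorm <- sapply(1:10, function(s) count_excl(TRUE, s))
  expect_true(all(renorm <= naive))
  expect_lt(sum(renorm), sum(naive))
})

test_that("conet is deterministic and returns signed taxon-taxon edges", {
  st <- generate_study(small_config(seed = 12))
  net <- conet(st$abundance, st$metadata, top_n = 100, bottom_n = 100,
               iterations = 200, seed = 5)
  expect_s3_class(net, "mm_network")
  expect_true(all(net$nodes$type == "taxon"))
  expect_true(all(net$edges$sign %in% c(-1L, 1L)))
  expect_true(all(net$edges$support >= 2))
  net2 <- conet(st$abundance, st$metadata, top_n = 100, bottom_n = 100,
                iterations = 200, seed = 5)
  expect_identical(net$edges, net2$edges)
})
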