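# Metrics, threshold sweeps, joint SFS, composite likelihood.

test_that("precision_recall counts correctly and reports NA denominators", {
  diag_tab <- confusion_table(rep(SCENARIO_CLASSES, each = 5),
                              rep(SCENARIO_CLASSES, each = 5))
  rep1 <- precision_recall(diag_tab)
  expect_true(all(rep1$per_class$precision == 1))
  expect_true(all(rep1$per_class$recall == 1))
  # true ELtoIL 10: predicted 8 ELtoIL + 2 none; true none 10: all none
  truth <- c(rep("ELtoIL", 10), rep("none", 10))
  pred <- c(rep("ELtoIL", 8), rep("none", 12))
  rep2 <- precision_recall(confusion_table(truth, pred))
  expect_equal(rep2$per_class$precision[1], 1.0)
  expect_equal(rep2$per_class$recall[1], 0.8)
  # a class never predicted: precision absent (NA), recall 0
  expect_true(is.na(rep2$per_class$precision[2]))
  expect_equal(rep2$per_class$recall[2], NA_real_) # ILtoEL never simulated
  truth3 <- c(rep("ILtoEL", 4), rep("none", 4))
  pred3 <- rep("none", 8)
  rep3 <- precision_recall(confusion_table(truth3, pred3))
  expect_true(is.na(rep3$per_class$precision[2]))
  expect_equal(rep3$per_class$recall[2], 0)
})

test_that("threshold sweep has five rows and P = 1 sanity behavior", {
  set.seed(4)
  n <- 200
  probs <- matrix(rexp(4 * n), ncol = 4)
  probs <- probs / rowSums(probs)
  truth <- sample(SCENARIO_CLASSES, n, replace = TRUE)
  tab <- evaluate_thresholds(probs, truth)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$p, c(0.75, 0.8, 0.85, 0.9, 0.95))
  # strict threshold: zero positive calls, presence recall 0
  t1 <- evaluate_thresholds(probs, truth, p_values = 1.0)
  expect_equal(t1$presence_recall, 0)
  expect_true(is.na(t1$presence_precision))
})

test_that("joint_sfs counts sites by per-population allele counts", {
  # one site at count (3, 0) in samples (4, 4)
  mat <- matrix(0L, nrow = 8, ncol = 1)
  mat[1:3, 1] <- 1L
  sfs <- joint_sfs(mat, pop_sizes = c(4L, 4L))
  expect_equal(sfs[4, 1], 1L) # cell (3, 0) is [4, 1] in 1-based indexing
  expect_equal(sum(sfs), 1L)
  # matrix total = segregating site count
  aln <- toy_alignment(n = 12, s = 150, pop_sizes = c(6, 6))
  sfs2 <- joint_sfs(aln)
  expect_equal(sum(sfs2), 150L)
  # monomorphic-only input -> all mass in the (0, 0) corner
  mono <- haplotype_alignment(matrix(0L, 8, 3), c(10, 20, 30), c(4L, 4L))
  sfs3 <- joint_sfs(mono)
  expect_equal(sfs3[1, 1], 3L)
  expect_equal(sum(sfs3), 3L)
})

test_that("ll_multinom matches a brute-force oracle and is scale-invariant", {
  data <- matrix(c(0, 2, 1, 0), 2, 2)
  model <- matrix(c(0, 1, 1, 0), 2, 2)
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2) # corners masked
  # brute force: theta = 3/2; cells (2|1.5), (1|1.5)
  theta <- 3 / 2
  oracle <- (2 * log(theta * 1) - theta * 1 - lgamma(3)) +
    (1 * log(theta * 1) - theta * 1 - lgamma(2))
  expect_equal(ll_multinom(data, model, mask), oracle)
  # scaling invariance: LL(data, c*model) = LL(data, model)
  expect_equal(ll_multinom(data, 7.3 * model, mask),
               ll_multinom(data, model, mask))
  # self-likelihood optimality among same-total models
  d2 <- matrix(c(0, 5, 3, 2, 1, 0), 2, 3)
  self_ll <- ll_multinom(d2, d2)
  set.seed(31)
  for (i in 1:25) {
    alt <- matrix(rexp(6), 2, 3)
    alt <- alt * sum(d2) / sum(alt)
    expect_lte(ll_multinom(d2, alt), self_ll + 1e-9)
  }
  expect_warning(v <- ll_multinom(matrix(c(0, 1, 1, 0), 2, 2),
                                  matrix(c(0, 0, 1, 0), 2, 2)),
                 "zero")
  expect_identical(v, -Inf)
})

test_that("depth sweep sets alter fewer genotypes at higher depth", {
  m <- test_model()
  sets <- cached("depth_sweep", build_depth_sweep_sets(
    m, per_scenario = 3L, lambdas = c(2, 6), seed = 61, region_bp = 2e5,
    samples = small_samples()))
  changed <- vapply(sets, function(s) {
    sum(vapply(s$examples, function(e) attr(e$alignment, "n_changed"), 0))
  }, 0)
  expect_gt(changed[["lambda2"]], changed[["lambda6"]])
  expect_length(sets$lambda2$examples, 12L) # n per scenario x 4 classes
})

test_that("realistic set corrupts only designated individuals and scales rates", {
  m <- test_model()
  rs <- cached("realistic_set", build_realistic_set(
    m, per_scenario = 3L, low_depth = c(2L, 1L), seed = 62,
    region_bp = 2e5, samples = small_samples()))
  expect_length(rs$examples, 12L)
  expect_equal(length(rs$rate_scales), 12L)
  expect_true(all(rs$rate_scales > 0))
  # ELs-style designation: exactly 1 corrupted individual on population 2
  # (verified structurally: only designated rows may differ from base run)
  base <- build_realistic_set(m, per_scenario = 3L, low_depth = c(0L, 0L),
                              heterogeneity = NULL, seed = 63,
                              region_bp = 2e5, samples = small_samples())
  expect_true(all(vapply(base$examples, function(e) {
    is.null(attr(e$alignment, "n_changed"))
  }, TRUE))) # zero low-depth + no heterogeneity leaves alignments untouched
  expect_error(build_realistic_set(m, 2L, low_depth = c(99L, 0L),
                                   samples = small_samples(), seed = 1),
               "low_depth")
})
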