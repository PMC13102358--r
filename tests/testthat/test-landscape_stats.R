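# Window statistics, random nulls, effect sizes, correlations.

test_that("nucleotide_diversity matches the closed form", {
  # one site with p = 0.5 among n = 4 haplotypes, span 1000 bp
  mat <- matrix(c(1, 1, 0, 0), ncol = 1)
  expect_equal(nucleotide_diversity(mat, 1000), (2 * 0.25 * 4 / 3) / 1000)
  expect_equal(nucleotide_diversity(matrix(0, 4, 5), 1000), 0) # monomorphic
  # invariant under ref/alt relabeling
  set.seed(2)
  m <- matrix(rbinom(8 * 20, 1, 0.4), nrow = 8)
  expect_equal(nucleotide_diversity(m, 500),
               nucleotide_diversity(1 - m, 500))
  expect_error(nucleotide_diversity(m, 0), "positive")
})

test_that("telomere_distance takes the closest end", {
  expect_equal(telomere_distance(0, 100, 1000), 0)
  expect_equal(telomere_distance(400, 600, 1000), 400)
  expect_equal(telomere_distance(900, 950, 1000), 50)
  expect_error(telomere_distance(900, 1100, 1000), "bounds")
})

test_that("gene_overlap uses the union of gene intervals", {
  genes <- data.frame(start = c(50, 70), end = c(80, 120))
  expect_equal(gene_overlap(0, 100, genes), 50) # union [50,120) clipped
  expect_equal(gene_overlap(0, 100, genes[0, ]), 0)
  whole <- data.frame(start = 0, end = 200)
  expect_equal(gene_overlap(20, 90, whole), 70) # gene covers the window
})

test_that("random_null reproduces the observed length multiset in bounds", {
  lens <- c(chr1 = 5e6, chr2 = 2e6)
  obs <- c(10000, 25000, 40000, 70000)
  nulls <- random_null(obs, lens, replicates = 100, seed = 5)
  expect_length(nulls, 100L)
  for (r in nulls[c(1, 50, 100)]) {
    expect_equal(sort(r$bp_end - r$bp_start), sort(obs))
    expect_true(all(r$bp_start >= 0))
    expect_true(all(r$bp_end <= lens[r$chrom]))
  }
  expect_error(random_null(3e6, c(chr1 = 2e6), seed = 1), "longer")
})

test_that("random telomere distance approaches the analytic expectation", {
  # single chromosome of length L, window length w, start U ~ Unif(0, L-w):
  # E[min(U, L-w-U)] = (L-w)/4
  L <- 1e6
  w <- 50000
  nulls <- random_null(rep(w, 40), c(chr = L), replicates = 50, seed = 8)
  d <- unlist(lapply(nulls, function(r) {
    telomere_distance(r$bp_start, r$bp_end, L)
  }))
  expected <- (L - w) / 4
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected), 4 * se)
})

test_that("random_null replicates are exchangeable", {
  lens <- c(chr1 = 5e6, chr2 = 2e6)
  nulls <- random_null(rep(30000, 30), lens, replicates = 40, seed = 17)
  tds <- lapply(nulls, function(r) {
    telomere_distance(r$bp_start, r$bp_end, lens[r$chrom])
  })
  ks <- suppressWarnings(stats::ks.test(tds[[3]], tds[[37]]))
  expect_gt(ks$p.value, 0.001)
})

test_that("compare_groups matches the log-shift oracle", {
  a <- exp(c(-1, 0, 1))
  res0 <- compare_groups(a, a) # identical groups
  expect_equal(res0$cd, 0)
  expect_equal(res0$p_value, 1)
  # group shifted by factor e with SD of logs = 1 -> Cd = 1
  res1 <- compare_groups(a * exp(1), a)
  expect_equal(res1$cd, 1)
  # swapping groups flips the sign, p unchanged
  res2 <- compare_groups(a, a * exp(1))
  expect_equal(res2$cd, -1)
  expect_equal(res2$p_value, res1$p_value)
})

test_that("compare_groups handles zeros via the half-minimum floor", {
  obs <- c(0, 2, 4, 8)
  nul <- c(1, 2, 3, 4)
  res <- compare_groups(obs, nul)
  expect_true(is.finite(res$cd))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_error(compare_groups(c(2, 2), c(4, 4)), "zero variance")
})

test_that("chromosome_correlation matches a direct formula oracle", {
  x <- c(0.12, 0.08, 0.15, 0.03, 0.09)
  l <- c(20e6, 35e6, 12e6, 50e6, 28e6)
  res <- chromosome_correlation(x, l)
  r_manual <- sum((x - mean(x)) * (l - mean(l))) /
    sqrt(sum((x - mean(x))^2) * sum((l - mean(l))^2))
  expect_equal(res$r, r_manual)
  tstat <- r_manual * sqrt(3 / (1 - r_manual^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 3))
  # exact linear relation -> |r| = 1
  expect_equal(abs(chromosome_correlation(l * 2e-9, l)$r), 1)
  # permutation of paired order leaves r unchanged
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(chromosome_correlation(x[perm], l[perm])$r, res$r)
  expect_error(chromosome_correlation(rep(1, 4), l[1:4]), "variance")
})

test_that("telomere-enriched regions recover the expected sign pattern", {
  # constructed landscape: "introgressed" windows near chromosome ends have
  # smaller telomere distance than random nulls -> Cd > 0 with the null-minus
  # -observed orientation flipped (positive means observed larger; distance
  # should be smaller, so cd < 0 with observed-minus-null orientation)
  lens <- c(chr1 = 10e6, chr2 = 8e6)
  obs <- data.frame(chrom = rep(c("chr1", "chr2"), each = 10),
                    bp_start = rep(c(seq(0, 450000, by = 50000)), 2))
  obs$bp_end <- obs$bp_start + 50000
  nulls <- random_null(rep(50000, 20), lens, replicates = 30, seed = 3)
  td_obs <- telomere_distance(obs$bp_start, obs$bp_end, lens[obs$chrom])
  td_null <- unlist(lapply(nulls, function(r) {
    telomere_distance(r$bp_start, r$bp_end, lens[r$chrom])
  }))
  res <- compare_groups(td_obs, td_null)
  expect_lt(res$cd, 0) # observed distances smaller
  expect_lt(res$p_value, 0.001)
})
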