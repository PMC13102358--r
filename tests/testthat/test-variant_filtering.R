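# Site-level and window-level variant filters.

test_that("filter_site applies the quality rules with first-fail reasons", {
  cfg <- filter_config()
  sites <- data.frame(
    chrom = "chr1",
    pos = c(100, 200, 300, 400, 500, 600),
    biallelic = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    FS = c(70, 10, 10, 10, 10, NA),
    MQ = c(50, 50, 50, 40, 50, NA),
    QD = c(10, 6.0, 5.99, 10, 10, NA))
  res <- filter_site(sites, cfg)
  # FS = 70 >= 60 -> drop; all thresholds passed (QD < 6 strict) -> keep;
  # QD = 5.99 -> drop; MQ <= 40 -> drop; non-biallelic -> drop;
  # absent annotations -> keep
  expect_equal(res$keep, c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$reason[c(1, 3, 4, 5)],
               c("FS", "QD", "MQ", "not_biallelic"))
})

test_that("filter_site honors the repeat mask and rule precedence", {
  mask <- data.frame(chrom = "chr1", start = 150, end = 250)
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 249, 250),
                      biallelic = TRUE, FS = c(10, 70, 10, 10),
                      MQ = 50, QD = 10)
  res <- filter_site(sites, filter_config(), repeat_mask = mask)
  expect_equal(res$keep, c(TRUE, FALSE, FALSE, TRUE)) # half-open mask
  expect_equal(res$reason[2], "repeat_mask") # mask outranks FS
})

test_that("site-level filter composition is order-independent", {
  set.seed(7)
  n <- 500
  sites <- data.frame(
    chrom = "chr1", pos = sort(sample.int(1e6, n)),
    biallelic = runif(n) > 0.05,
    FS = rexp(n, 1 / 30), MQ = runif(n, 20, 60), QD = runif(n, 0, 20))
  keep_joint <- filter_site(sites, filter_config())$keep
  # apply single rules independently and intersect
  keep_rules <- sites$biallelic &
    !(sites$FS >= 60) & !(sites$MQ <= 40) & !(sites$QD < 6)
  expect_equal(keep_joint, keep_rules)
})

test_that("missingness_filter drops at >= 15% within the population", {
  # 4 of 22 = 18.2% -> drop; 3 of 22 = 13.6% -> keep; 0 missing -> keep
  expect_equal(missingness_filter(c(4L, 3L, 0L), 22L),
               c(FALSE, TRUE, TRUE))
  expect_error(missingness_filter(c(1L), 0L), "at least one")
  # matrix form
  m <- matrix(FALSE, nrow = 22, ncol = 2)
  m[1:4, 1] <- TRUE
  expect_equal(missingness_filter(m), c(FALSE, TRUE))
})

test_that("depth_window_filter excludes windows above 1.5x the binned mode", {
  # mode 100, threshold 150 -> window 4 excluded
  expect_equal(depth_window_filter(c(100, 100, 100, 200)),
               c(FALSE, FALSE, FALSE, TRUE))
  # all equal: value = mode < 1.5x mode -> nothing excluded
  expect_false(any(depth_window_filter(rep(42, 10))))
  # binned-mode oracle: mode 10, threshold 15, only the 16 window excluded
  expect_equal(depth_window_filter(c(10, 10, 14, 16)),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_error(depth_window_filter(c(0, 0, 0)), "degenerate")
})

test_that("depth_window_filter properties: mode ties and never-below-mode", {
  # tie between 10 and 20 -> smallest modal value (10) used -> 20 > 15 excluded
  expect_equal(depth_window_filter(c(10, 10, 20, 20, 30)),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  set.seed(11)
  for (i in 1:20) {
    sums <- rpois(50, 40)
    excl <- depth_window_filter(sums)
    m <- introscan:::.binned_mode(sums)
    expect_false(any(excl[sums <= m])) # never excludes a window at/below mode
  }
})

test_that("thin_sites performs the greedy >= thin_bp scan", {
  expect_equal(thin_sites(c(1, 40000, 95000), 50000), c(1, 95000))
  expect_equal(thin_sites(123), 123) # single position retained
  # spacing exactly thin_bp everywhere -> all retained (vcftools convention)
  pos <- seq(0, 250000, by = 50000)
  expect_equal(thin_sites(pos, 50000), pos)
  expect_error(thin_sites(c(5, 1)), "sorted")
})

test_that("thin_sites output spacing >= thin_bp on random inputs", {
  set.seed(3)
  for (i in 1:25) {
    pos <- sort(sample.int(5e5, 200))
    out <- thin_sites(pos, 30000)
    if (length(out) > 1) expect_true(all(diff(out) >= 30000))
    expect_equal(out[1], pos[1]) # first site always kept
  }
})

test_that("exclude_genic respects half-open gene intervals", {
  genes <- data.frame(start = 100, end = 200)
  expect_equal(exclude_genic(c(99, 100, 150, 199, 200, 201), genes),
               c(99, 200, 201)) # end coordinate retained
  pos <- c(1, 5, 9)
  expect_equal(exclude_genic(pos, genes[0, ]), pos) # empty genes -> identity
  # brute-force membership oracle: 10 positions, one gene covering 4
  pos10 <- seq(0, 90, by = 10)
  g <- data.frame(start = 25, end = 65) # covers 30, 40, 50, 60
  manual <- pos10[!(pos10 >= 25 & pos10 < 65)]
  expect_equal(exclude_genic(pos10, g), manual)
  expect_length(manual, 6)
})
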