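# Decision rule, neighbor relaxation, merging, fractions, scan unions.

test_that("assign_class reproduces the stated rule cases", {
  expect_equal(assign_class(c(0.95, 0.01, 0.02, 0.02), 0.9), "ELtoIL")
  expect_equal(assign_class(c(0.05, 0.05, 0.88, 0.02), 0.9), "BiDir")
  expect_equal(assign_class(c(0.40, 0.40, 0.10, 0.10), 0.9), "none")
  expect_equal(assign_class(c(0.01, 0.95, 0.02, 0.02), 0.9), "ILtoEL")
})

test_that("assign_class is monotone in P and all-none at P = 1", {
  set.seed(13)
  probs <- matrix(rexp(400), ncol = 4)
  probs <- probs / rowSums(probs)
  ps <- seq(0.55, 0.99, by = 0.02)
  prev_called <- rep(TRUE, nrow(probs))
  for (p in ps) {
    called <- assign_class(probs, p) != "none"
    expect_true(all(called <= prev_called)) # raising P never creates calls
    prev_called <- called
  }
  expect_true(all(assign_class(probs, 1) == "none")) # strict inequality
})

.mk_calls <- function(chrom, probs, p = 0.9) {
  n <- nrow(probs)
  windows <- data.frame(snp_start = seq(1, by = 64, length.out = n),
                        snp_end = seq(128, by = 64, length.out = n),
                        bp_start = seq(0, by = 6400, length.out = n),
                        bp_end = seq(12800, by = 6400, length.out = n))
  window_calls(windows, probs, chrom = chrom,
               config = caller_config(p = p))
}

test_that("neighbor_extension relaxes only adjacent none-windows, one pass", {
  # chain: none(0.75) - none(0.75) - primary
  probs <- rbind(c(0.75, 0.05, 0.0, 0.20),
                 c(0.75, 0.05, 0.0, 0.20),
                 c(0.95, 0.01, 0.02, 0.02))
  calls <- .mk_calls("chr1", probs)
  expect_equal(calls$class, c("none", "none", "ELtoIL"))
  ext <- neighbor_extension(calls, caller_config())
  # only the window touching the primary call flips; no propagation
  expect_equal(ext$class, c("none", "ELtoIL", "ELtoIL"))
  expect_equal(ext$stage, c("none", "neighbor-extended", "primary"))
  # identical window with no adjacent call stays none
  iso <- .mk_calls("chr1", rbind(c(0.75, 0.05, 0.0, 0.20),
                                 c(0.1, 0.1, 0.1, 0.7)))
  expect_equal(neighbor_extension(iso, caller_config())$class,
               c("none", "none"))
})

test_that("neighbor_extension never changes primary calls nor crosses chromosomes", {
  probs <- rbind(c(0.95, 0.01, 0.02, 0.02), # chr1 primary
                 c(0.75, 0.05, 0.0, 0.20)) # chr2 would qualify if adjacent
  calls <- rbind(.mk_calls("chr1", probs[1, , drop = FALSE]),
                 .mk_calls("chr2", probs[2, , drop = FALSE]))
  ext <- neighbor_extension(calls, caller_config())
  expect_equal(ext$class, c("ELtoIL", "none"))
  expect_equal(ext$stage[1], "primary")
  # unordered input within a chromosome is rejected
  disordered <- .mk_calls("chr1", probs)
  disordered <- disordered[c(2, 1), ]
  expect_error(neighbor_extension(disordered, caller_config()), "ordered")
})

test_that("merge_calls merges consecutive same-class windows", {
  probs <- rbind(c(0.95, 0.01, 0.02, 0.02),
                 c(0.93, 0.02, 0.03, 0.02))
  calls <- .mk_calls("chr1", probs)
  merged <- merge_calls(calls)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$bp_start, 0)
  expect_equal(merged$bp_end, calls$bp_end[2]) # bp union of both windows
  expect_equal(merged$n_windows, 2L)
  # different classes never merge
  probs2 <- rbind(c(0.95, 0.01, 0.02, 0.02), c(0.01, 0.95, 0.02, 0.02))
  expect_equal(nrow(merge_calls(.mk_calls("chr1", probs2))), 2L)
  # alternating call/none/call -> two regions
  probs3 <- rbind(c(0.95, 0.01, 0.02, 0.02), c(0.1, 0.1, 0.1, 0.7),
                  c(0.95, 0.01, 0.02, 0.02))
  expect_equal(nrow(merge_calls(.mk_calls("chr1", probs3))), 2L)
})

test_that("genome_fraction flattens overlaps and validates bounds", {
  lens <- c(chrA = 60e6, chrB = 40e6)
  regions <- data.frame(chrom = "chrA", bp_start = c(0, 2e6),
                        bp_end = c(4e6, 8e6), class = "ELtoIL",
                        n_windows = 1L)
  fr <- genome_fraction(regions, lens)
  expect_equal(fr$overall, 8e6 / 100e6)
  expect_equal(unname(fr$per_class["ELtoIL"]), 0.08)
  # 6 Mbp of regions on a 100 Mbp genome -> 0.06
  r2 <- data.frame(chrom = "chrB", bp_start = 0, bp_end = 6e6,
                   class = "ILtoEL", n_windows = 1L)
  expect_equal(genome_fraction(r2, lens)$overall, 0.06)
  expect_equal(genome_fraction(regions[0, ], lens)$overall, 0)
  # two overlapping 1 Mbp regions with 0.5 Mbp overlap -> 1.5 Mbp counted
  r3 <- data.frame(chrom = "chrA", bp_start = c(0, 0.5e6),
                   bp_end = c(1e6, 1.5e6), class = "ELtoIL", n_windows = 1L)
  expect_equal(genome_fraction(r3, lens)$overall, 1.5e6 / 100e6)
  bad <- data.frame(chrom = "chrA", bp_start = 0, bp_end = 70e6,
                    class = "ELtoIL", n_windows = 1L)
  expect_error(genome_fraction(bad, lens), "bounds")
})

test_that("merging is fraction-invariant", {
  set.seed(21)
  probs <- matrix(rexp(4 * 40), ncol = 4)
  probs <- probs / rowSums(probs)
  probs[sample(40, 15), 1] <- 3 # force some strong ELtoIL runs
  probs <- probs / rowSums(probs)
  calls <- .mk_calls("chr1", probs, p = 0.8)
  lens <- c(chr1 = 1e6)
  merged_fr <- genome_fraction(merge_calls(calls), lens)$overall
  flat <- calls[calls$class != "none", ]
  flat$n_windows <- 1L
  unmerged_fr <- genome_fraction(flat, lens)$overall
  expect_equal(merged_fr, unmerged_fr)
})

test_that("union_scans partitions exactly", {
  lens <- c(chr1 = 100)
  a <- data.frame(chrom = "chr1", bp_start = 0, bp_end = 10,
                  class = "ELtoIL", n_windows = 1L)
  b <- data.frame(chrom = "chr1", bp_start = 5, bp_end = 15,
                  class = "ELtoIL", n_windows = 1L)
  u <- union_scans(a, b, lens)
  expect_equal(unname(u$fractions),
               c(5 / 100, 5 / 100, 5 / 100, 15 / 100))
  # disjoint sets -> empty intersection
  b2 <- transform(b, bp_start = 50, bp_end = 60)
  u2 <- union_scans(a, b2, lens)
  expect_equal(unname(u2$fractions["both"]), 0)
  # partition identity mirrors 1.92 + 0.97 + 3.63 = 6.52
  set.seed(8)
  ra <- data.frame(chrom = "chr1", bp_start = s <- sort(sample(0:80, 6)),
                   bp_end = s + 7, class = "ELtoIL", n_windows = 1L)
  rb <- data.frame(chrom = "chr1", bp_start = s2 <- sort(sample(0:80, 6)),
                   bp_end = s2 + 9, class = "ELtoIL", n_windows = 1L)
  u3 <- union_scans(ra, rb, lens)
  expect_equal(sum(u3$fractions[c("a_only", "b_only", "both")]),
               unname(u3$fractions["union"]))
})
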