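# Truth-annotated synthetic cohort generation.

# Desk-scale cohort: study-design sample sizes but 2 short chromosomes, so
# the whole suite stays inside a CPU budget.
small_cohort_config <- function(seed = 1L, missing_rate = 0.03) {
  cohort_config(individuals = c(22L, 20L), n_chromosomes = 2L,
                chromosome_lengths = c(1.2e6, 0.8e6),
                low_depth_individuals = c(4L, 4L),
                missing_rate = missing_rate, seed = seed)
}

test_that("cohort_config validates its invariants", {
  expect_s3_class(cohort_config(), "cohort_config") # study-design defaults
  expect_equal(cohort_config()$individuals, c(22L, 20L))
  expect_equal(cohort_config()$n_chromosomes, 18L)
  expect_error(cohort_config(individuals = c(0L, 5L)), "individuals")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(n_chromosomes = 3L,
                             chromosome_lengths = c(1e6, 1e6)),
               "chromosome_lengths")
})

test_that("generate_annotations hits the target density within 10%", {
  cfg <- cohort_config(n_chromosomes = 5L,
                       chromosome_lengths = rep(10e6, 5), seed = 3L)
  ann <- generate_annotations(cfg, gene_density = 0.3, repeat_density = 0.2)
  genome <- sum(cfg$chromosome_lengths)
  gene_bp <- sum(ann$genes$end - ann$genes$start)
  expect_gt(gene_bp / genome, 0.27)
  expect_lt(gene_bp / genome, 0.33)
  # intervals sorted, half-open, non-negative, in bounds per chromosome
  for (ch in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, ]
    expect_true(all(g$start >= 0))
    expect_true(all(g$end > g$start))
    expect_true(all(g$end <= 10e6))
    expect_false(is.unsorted(g$start))
  }
  # density 0 -> empty track; density > 1 -> error
  expect_equal(nrow(generate_annotations(cfg, gene_density = 0)$genes), 0L)
  expect_error(generate_annotations(cfg, gene_density = 1.5), "gene_density")
})

test_that("generate_cohort emits the full artifact set with 42 samples", {
  dir <- withr::local_tempdir()
  cohort <- cached("cohort", generate_cohort(
    small_cohort_config(seed = 11L), test_model(),
    scenario_mix = c(none = 0.5, ELtoIL = 0.5), out_dir = dir))
  for (p in cohort$paths) expect_true(file.exists(p))
  hdr <- readLines(cohort$paths$vcf, n = 20)
  cols <- strsplit(hdr[startsWith(hdr, "#CHROM")], "\t")[[1]]
  expect_length(cols, 9 + 42) # 22 + 20 diploid sample columns
  expect_true(any(grepl("fileformat=VCFv4.2", hdr)))
  # depth table covers every individual and 10-kbp tile
  expect_equal(sort(unique(cohort$depth$individual)), 1:42)
  expect_equal(nrow(cohort$depth), 42 * (120 + 80))
})

test_that("an all-none scenario mix yields an empty truth set", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(individuals = c(4L, 4L), n_chromosomes = 2L,
                       chromosome_lengths = c(4e5, 3e5),
                       low_depth_individuals = c(1L, 1L), seed = 21L)
  cohort <- generate_cohort(cfg, test_model(),
                            scenario_mix = c(none = 1), out_dir = dir)
  expect_equal(nrow(cohort$truth$tracts), 0L)
  expect_true(all(vapply(cohort$truth$flags, sum, 0) == 0))
})

test_that("same seed gives byte-identical VCF output", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- cohort_config(individuals = c(4L, 4L), n_chromosomes = 1L,
                       chromosome_lengths = 3e5,
                       low_depth_individuals = c(1L, 1L), seed = 33L)
  c1 <- generate_cohort(cfg, test_model(), c(none = 0.5, ELtoIL = 0.5), d1)
  c2 <- generate_cohort(cfg, test_model(), c(none = 0.5, ELtoIL = 0.5), d2)
  expect_identical(readBin(c1$paths$vcf, "raw", file.size(c1$paths$vcf)),
                   readBin(c2$paths$vcf, "raw", file.size(c2$paths$vcf)))
})

test_that("the VCF round-trips to an identical haplotype alignment", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(individuals = c(5L, 3L), n_chromosomes = 1L,
                       chromosome_lengths = 4e5,
                       low_depth_individuals = c(0L, 0L),
                       missing_rate = 0, seed = 44L)
  cohort <- generate_cohort(cfg, test_model(), c(none = 1), out_dir = dir)
  vcf <- read_cohort_vcf(cohort$paths$vcf)
  alns <- phased_alignments(vcf, pop_sizes = c(5L, 3L),
                            populations = c("ILa", "ELw"))
  orig <- cohort$alignments$chr1
  expect_identical(alns$chr1$mat, orig$mat)
  expect_equal(alns$chr1$positions, orig$positions)
  expect_equal(alns$chr1$pop_sizes, orig$pop_sizes)
})

test_that("realized VCF missingness matches the configured rate", {
  dir <- withr::local_tempdir()
  rate <- 0.05
  cfg <- cohort_config(individuals = c(6L, 6L), n_chromosomes = 1L,
                       chromosome_lengths = 6e5,
                       low_depth_individuals = c(1L, 1L),
                       missing_rate = rate, seed = 55L)
  cohort <- generate_cohort(cfg, test_model(), c(none = 1), out_dir = dir)
  vcf <- read_cohort_vcf(cohort$paths$vcf)
  n_calls <- length(vcf$gt1)
  n_missing <- sum(is.na(vcf$gt1))
  se <- sqrt(rate * (1 - rate) / n_calls)
  expect_lt(abs(n_missing / n_calls - rate), 4 * se)
})

test_that("introgression truth is consistent with recorded tracts", {
  cohort <- cached("cohort", stop("populated by earlier test"))
  tr <- cohort$truth$tracts
  labels <- cohort$truth$labels
  lens <- cohort$chrom_lengths
  intro_chroms <- names(labels)[labels == "ELtoIL"]
  if (length(intro_chroms) > 0) {
    # each pulse chromosome records >= 1 recipient haplotype with a tract
    expect_true(all(intro_chroms %in% tr$chrom))
    for (ch in intro_chroms) {
      expect_gte(sum(cohort$truth$flags[[ch]][1:44]), 1)
    }
    # tract intervals lie within chromosome bounds
    expect_true(all(tr$bp_start >= 0))
    expect_true(all(tr$bp_end <= lens[tr$chrom]))
    # recipient population matches the pulse direction (into the Iberian side)
    expect_true(all(tr$recipient == "ILa"))
  }
  # per-haplotype tracts stay within their chromosome too
  ht <- cohort$truth$hap_tracts
  expect_true(all(ht$right <= lens[ht$chrom]))
})
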