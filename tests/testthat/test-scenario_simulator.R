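# Scenario draws, rate heterogeneity, simulation, error injection,
# training-set assembly.

test_that("draw_scenario respects the stated parameter ranges", {
  set.seed(101)
  draws <- replicate(1e5, {
    s <- draw_scenario("ELtoIL")
    c(s$pulses[[1]]$proportion, s$pulses[[1]]$time)
  })
  expect_true(all(draws[1, ] >= 0.05 & draws[1, ] <= 0.50))
  expect_true(all(draws[2, ] >= 1 & draws[2, ] <= 5000))
  # mean of uniform(0.05, 0.50) with Monte-Carlo slack
  expect_lt(abs(mean(draws[1, ]) - 0.275), 0.005)
  expect_length(draw_scenario("none")$pulses, 0L)
  bi <- draw_scenario("BiDir")
  expect_setequal(vapply(bi$pulses, `[[`, 0L, "recipient"), 1:2)
})

test_that("scenario_spec enforces label/pulse consistency", {
  expect_error(scenario_spec("none", list(list(recipient = 1L, donor = 2L,
                                               proportion = 0.2, time = 10))),
               "implies no pulses")
  expect_error(scenario_spec("ELtoIL", list()), "exactly one pulse")
  expect_error(scenario_spec("ELtoIL",
                             list(list(recipient = 1L, donor = 2L,
                                       proportion = 0.01, time = 10))),
               "proportion")
})

test_that("rate scalers have mean 1 and variance 1/alpha", {
  set.seed(55)
  x <- sample_rate_scaler(rate_heterogeneity_config(), n = 1e5)
  expect_true(all(x > 0))
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 1), 3 * se_mean)
  expect_lt(abs(var(x) - 0.1), 0.005)
})

test_that("simulate_example flags recipient haplotypes per scenario", {
  m <- test_model()
  ex <- cached("flag_examples", {
    specs <- list(scenario_spec("none"),
                  with_seed(41, draw_scenario("ELtoIL")),
                  with_seed(42, draw_scenario("ILtoEL")),
                  with_seed(43, draw_scenario("BiDir")))
    simulate_examples(m, specs, region_bp = 3e5, seed = 77)
  })
  n1 <- 44L # 22 diploids on the Iberian side
  f <- lapply(ex, function(e) {
    list(p1 = sum(e$flags[seq_len(n1)]), p2 = sum(e$flags[-seq_len(n1)]))
  })
  expect_equal(f[[1]]$p1 + f[[1]]$p2, 0) # none: nothing flagged
  expect_gte(f[[2]]$p1, 1) # ELtoIL: Iberian-side haplotype flagged
  expect_equal(f[[2]]$p2, 0)
  expect_gte(f[[3]]$p2, 1)
  expect_gte(f[[4]]$p1, 1) # BiDir: both directions
  expect_gte(f[[4]]$p2, 1)
  expect_gte(ncol(ex[[1]]$alignment$mat), 128L)
  # truth consistency: flagged haplotypes have recorded tracts
  tr <- ex[[2]]$tracts
  expect_setequal(unique(tr$hap), which(ex[[2]]$flags == 1))
})

test_that("inject_depth_errors follows the allelic-dropout model", {
  # forced d = 1 at het sites -> call always becomes homozygous
  s <- 400L
  mat <- rbind(rep(0L, s), rep(1L, s)) # one individual, all het
  aln <- haplotype_alignment(mat, seq_len(s) * 10, pop_sizes = c(1L, 1L))
  cfg1 <- depth_error_config(lambda = 1e-9, min_depth = 1L)
  out <- inject_depth_errors(aln, cfg1, seed = 5)
  expect_true(all(out$mat[1, ] == out$mat[2, ])) # every call homozygous
  expect_equal(attr(out, "n_changed"), s)
  # homozygous sites are never altered
  hom <- haplotype_alignment(rbind(rep(1L, s), rep(1L, s)),
                             seq_len(s) * 10, pop_sizes = c(1L, 1L))
  out2 <- inject_depth_errors(hom, depth_error_config(2), seed = 6)
  expect_identical(out2$mat, hom$mat)
  expect_error(depth_error_config(lambda = 0), "lambda")
})

test_that("het-site miscall rate matches the brute-force expectation", {
  # oracle: E[2 (1/2)^d], d = max(1, Poisson(lambda)), enumerated to d = 60
  miscall_expect <- function(lambda) {
    d <- 1:60
    pr <- dpois(d, lambda)
    pr[1] <- pr[1] + dpois(0, lambda) # clamp d = 0 up to 1
    sum(pr * 2 * 0.5^d) / sum(pr)
  }
  n <- 1e5
  mat <- rbind(rep(0L, n), rep(1L, n))
  aln <- haplotype_alignment(mat, seq_len(n), pop_sizes = c(1L, 1L))
  for (lambda in c(2, 4, 6)) {
    out <- inject_depth_errors(aln, depth_error_config(lambda),
                               seed = 100 + lambda)
    p <- miscall_expect(lambda)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(attr(out, "n_changed") / n - p), 3 * se)
  }
})

test_that("depth errors vanish as lambda grows", {
  n <- 2000L
  mat <- rbind(rep(0L, n), rep(1L, n))
  aln <- haplotype_alignment(mat, seq_len(n), pop_sizes = c(1L, 1L))
  out <- inject_depth_errors(aln, depth_error_config(200), seed = 9)
  expect_lt(attr(out, "n_changed") / n, 1e-3)
})

test_that("pulse effect is monotone in the migration proportion", {
  # scaled down: 60 simulations per proportion instead of 200
  m <- test_model()
  n_rep <- 60L
  mk <- function(p) {
    specs <- replicate(n_rep, scenario_spec("ELtoIL", list(
      list(recipient = 1L, donor = 2L, proportion = p, time = 1000))),
      simplify = FALSE)
    ex <- simulate_examples(m, specs, region_bp = 1.5e5, seed = 500,
                            samples = small_samples(), min_sites = 20L)
    mean(vapply(ex, function(e) sum(e$flags[1:16]), 0))
  }
  lo <- cached("pulse_lo", mk(0.05))
  hi <- cached("pulse_hi", mk(0.50))
  expect_gt(hi, lo)
})

test_that("introgressed scenarios carry more cross-population shared variation", {
  # Under the representative fixture models (which include background
  # migration), a pulse homogenizes the pair: the robust SFS signature of
  # introgression is an excess of variants segregating in BOTH populations.
  # The narrower corner-cell statistic (opposite_frequency_mass) does not
  # discriminate in this regime; see the methods vignette.
  m <- test_model()
  shared_fraction <- function(aln) {
    sfs <- joint_sfs(aln, polarization = "derived")
    n1 <- nrow(sfs) - 1L
    n2 <- ncol(sfs) - 1L
    both <- sum(sfs[2:(n1 + 1L), 2:(n2 + 1L)])
    both / max(1, sum(sfs))
  }
  mk <- function(label, seed) {
    specs <- replicate(25, if (label == "none") scenario_spec("none") else
      scenario_spec("ELtoIL", list(list(recipient = 1L, donor = 2L,
                                        proportion = 0.4, time = 500))),
      simplify = FALSE)
    ex <- simulate_examples(m, specs, region_bp = 2e5, seed = seed,
                            samples = small_samples(), min_sites = 30L)
    mean(vapply(ex, function(e) shared_fraction(e$alignment), 0))
  }
  none_mass <- cached("sfs_none", mk("none", 311))
  el_mass <- cached("sfs_el", mk("ELtoIL", 312))
  expect_gt(el_mass, none_mass)
})

test_that("build_training_set accounts tensors and validation split", {
  dir <- withr::local_tempdir()
  m <- test_model()
  # desk-scale accounting run: 10 per scenario, one model
  store <- cached("tiny_store", build_training_set(
    list(m), per_scenario = 10L, dir = dir, seed = 88, region_bp = 2e5,
    H = 16L, samples = small_samples(), batch_size = 20L))
  ms <- manifest_summary(store)
  expect_equal(ms$total, 40L) # 10 x 4 labels x 1 model
  expect_true(all(ms$counts == 10L))
  expect_equal(unname(as.vector(ms$validation)), rep(1L, 4L)) # ceil(5% of 10)
  # label proportions exactly uniform by construction
  expect_equal(length(unique(table(store$records$label))), 1L)
  # tensors round-trip through the binary container
  x <- tensor_store_read(store, indices = c(1L, 40L))
  expect_equal(dim(x), c(2L, 16L, 128L, 2L))
  expect_true(all(x %in% c(0, 1)))
  raw <- tensor_store_read_raw(store)
  expect_equal(dim(raw), c(2L * 16L * 128L, 40L))
  expect_equal(as.integer(raw[, 1L]), as.integer(x[, , , 1L]))
})
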