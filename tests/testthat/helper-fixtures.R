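# Shared fixtures. Simulations are desk-scale: unit tests shrink region
# lengths and replicate counts relative to the full-scale study profile, and
# say so where a spec-level quantity is exercised at reduced size.

# default two-population model used across tests
test_model <- function() lynx_model("ILa-ELw", 1L)

# small sample sizes for tests that do not depend on the cohort design
small_samples <- function() c(ILa = 8L, ELw = 8L)

# deterministic toy alignment: n haplotypes x s sites
toy_alignment <- function(n = 8L, s = 200L, seed = 42L, chrom = "chr1",
                          pop_sizes = c(n / 2, n / 2)) {
  set.seed(seed)
  mat <- matrix(rbinom(n * s, 1L, 0.3), nrow = n)
  # ensure segregating, biallelic columns
  mat[1L, colSums(mat) == 0L] <- 1L
  mat[1L, colSums(mat) == n] <- 0L
  positions <- sort(sample.int(s * 50L, s))
  haplotype_alignment(mat, positions, pop_sizes = pop_sizes, chrom = chrom)
}

# linearly separable four-class tensor fixture: class-specific constant
# blocks on a sparse random background
make_separable_store <- function(n_per = 40L, H = 16L, W = 32L, seed = 1L,
                                 shuffle_labels = FALSE) {
  set.seed(seed)
  make_ex <- function(cls) {
    a <- array(as.numeric(runif(2 * H * W) < 0.2), dim = c(2L, H, W))
    if (cls == 1L) a[1L, 1:6, ] <- 1
    if (cls == 2L) a[2L, 1:6, ] <- 1
    if (cls == 3L) {
      a[1L, 1:6, ] <- 1
      a[2L, 1:6, ] <- 1
    }
    a
  }
  labs <- rep(1:4, each = n_per)
  tens <- array(0, dim = c(2L, H, W, length(labs)))
  for (i in seq_along(labs)) tens[, , , i] <- make_ex(labs[i])
  if (shuffle_labels) labs <- sample(labs)
  n_val <- max(2L, round(0.1 * n_per))
  val <- rep(c(rep(FALSE, n_per - n_val), rep(TRUE, n_val)), 4L)
  list(tensors = tens, labels = SCENARIO_CLASSES[labs], validation = val,
       make_ex = make_ex)
}

# memoized simulation batches shared across tests in one session
.test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}
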