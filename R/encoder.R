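# Tensor encoding of phased two-population haplotype alignments.
#
# Alignments are polarized per column to major/minor coding (major allele of
# the combined two-population sample codes 0), populations are upsampled to a
# shared haplotype count H by duplicating randomly chosen observed
# haplotypes, and 128-SNP windows with 64-SNP steps are assembled into
# (2, H, 128) binary tensors, one image layer per population.

#' Construct a phased haplotype alignment
#'
#' @param mat haplotypes x sites matrix with entries in {0, 1}; rows of
#'   population 1 first, then population 2.
#' @param positions bp position per site, strictly increasing.
#' @param pop_sizes integer(2), haplotype rows per population.
#' @param chrom chromosome identifier.
#' @param populations character(2) population labels.
#' @return a `haplotype_alignment`.
#' @export
haplotype_alignment <- function(mat, positions, pop_sizes, chrom = "chr1",
                                populations = c("pop1", "pop2")) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  stopifnot(all(mat %in% c(0L, 1L)), length(positions) == ncol(mat),
            length(pop_sizes) == 2L, sum(pop_sizes) == nrow(mat),
            all(pop_sizes > 0))
  if (ncol(mat) > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  structure(list(mat = mat, positions = as.numeric(positions),
                 pop_sizes = as.integer(pop_sizes), chrom = chrom,
                 populations = populations),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("<haplotype_alignment %s> %d + %d haplotypes, %d sites\n",
              x$chrom, x$pop_sizes[1], x$pop_sizes[2], ncol(x$mat)))
  invisible(x)
}

#' Rows of one population of an alignment
#' @param aln a [haplotype_alignment()].
#' @param pop 1 or 2.
#' @keywords internal
pop_rows <- function(aln, pop) {
  if (pop == 1L) seq_len(aln$pop_sizes[1])
  else aln$pop_sizes[1] + seq_len(aln$pop_sizes[2])
}

#' Polarize columns to major/minor coding
#'
#' Per column, the allele with frequency > 0.5 across the combined sample is
#' recoded as 0 and the minor allele as 1. Exact 50/50 ties keep the input
#' reference allele (coded 0 on input) as major. Idempotent; monomorphic
#' columns come out all-zero.
#'
#' @param x a {0,1} matrix (haplotypes x sites) or [haplotype_alignment()].
#' @return object of the same type, polarized.
#' @export
polarize <- function(x) {
  if (inherits(x, "haplotype_alignment")) {
    x$mat <- polarize(x$mat)
    return(x)
  }
  mat <- as.matrix(x)
  if (ncol(mat) == 0L) return(mat)
  flip <- colMeans(mat) > 0.5
  mat[, flip] <- 1L - mat[, flip, drop = FALSE]
  storage.mode(mat) <- "integer"
  mat
}

#' Upsample a population's haplotype rows to a target count
#'
#' All observed rows are retained once, in order; the remaining
#' `target - nrow` rows are drawn uniformly with replacement from the
#' observed rows and appended.
#'
#' @param rows haplotypes x sites matrix for one population.
#' @param target desired haplotype count H (>= nrow(rows)).
#' @param seed integer seed for the duplicate draw.
#' @return a `target` x sites matrix.
#' @export
upsample <- function(rows, target, seed = 1L) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  if (n > target) stop("population has more haplotypes (", n,
                       ") than target (", target, ")")
  if (n == target) return(rows)
  extra <- with_seed(seed, sample.int(n, target - n, replace = TRUE))
  rbind(rows, rows[extra, , drop = FALSE])
}

#' Enumerate sliding SNP windows over an alignment
#'
#' Windows start at SNP indices 0, `step_snps`, 2`step_snps`, ...; a trailing
#' window with fewer than `window_snps` SNPs is dropped, so the window count
#' is `floor((S - window_snps)/step_snps) + 1` for `S >= window_snps` and 0
#' otherwise.
#'
#' @param aln a [haplotype_alignment()] (or any object with `positions`).
#' @param window_snps SNPs per window (default 128).
#' @param step_snps step between window starts (default 64).
#' @return data.frame with columns `snp_start`, `snp_end` (1-based inclusive
#'   SNP indices), `bp_start`, `bp_end` (positions of the first and last SNP).
#' @export
extract_windows <- function(aln, window_snps = 128L, step_snps = 64L) {
  positions <- if (inherits(aln, "haplotype_alignment")) aln$positions
               else as.numeric(aln)
  s <- length(positions)
  if (s < window_snps) {
    return(data.frame(snp_start = integer(), snp_end = integer(),
                      bp_start = numeric(), bp_end = numeric()))
  }
  starts <- seq.int(1L, s - window_snps + 1L, by = step_snps)
  ends <- starts + window_snps - 1L
  data.frame(snp_start = starts, snp_end = ends,
             bp_start = positions[starts], bp_end = positions[ends])
}

#' Assemble a two-layer window tensor
#'
#' Layer 1 holds population 1 haplotypes, layer 2 population 2; both must
#' already be upsampled to the same H.
#'
#' @param rows1,rows2 H x W matrices for the two populations.
#' @return a (2, H, W) binary array.
#' @export
assemble_tensor <- function(rows1, rows2) {
  rows1 <- as.matrix(rows1)
  rows2 <- as.matrix(rows2)
  if (!identical(dim(rows1), dim(rows2))) {
    stop("populations must be upsampled to matching dimensions")
  }
  out <- array(0, dim = c(2L, nrow(rows1), ncol(rows1)))
  out[1L, , ] <- rows1
  out[2L, , ] <- rows2
  out
}

#' Encode an alignment into a batch of window tensors
#'
#' Applies per-window joint polarization, per-window seeded upsampling of
#' both populations to `H`, and sliding-window extraction. The upsampling
#' seed is derived from (`seed`, chromosome, window index) so scans are
#' reproducible window by window.
#'
#' @param aln a [haplotype_alignment()].
#' @param H padded haplotype dimension (default 44).
#' @param window_snps,step_snps window geometry (defaults 128 / 64).
#' @param seed master seed for upsampling.
#' @return list with `tensors` (array (2, H, window_snps, n)) and `windows`
#'   (the [extract_windows()] table).
#' @export
encode_alignment <- function(aln, H = 44L, window_snps = 128L,
                             step_snps = 64L, seed = 1L) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  wins <- extract_windows(aln, window_snps, step_snps)
  tensors <- array(0, dim = c(2L, H, window_snps, nrow(wins)))
  r1 <- pop_rows(aln, 1L)
  r2 <- pop_rows(aln, 2L)
  for (k in seq_len(nrow(wins))) {
    cols <- wins$snp_start[k]:wins$snp_end[k]
    sub <- polarize(aln$mat[, cols, drop = FALSE])
    s1 <- derive_seed(seed, paste0(aln$chrom, "/win", k, "/p1"))
    s2 <- derive_seed(seed, paste0(aln$chrom, "/win", k, "/p2"))
    tensors[, , , k] <- assemble_tensor(
      upsample(sub[r1, , drop = FALSE], H, s1),
      upsample(sub[r2, , drop = FALSE], H, s2))
  }
  list(tensors = tensors, windows = wins)
}

#' Encode the central window of a simulated region
#'
#' Training and evaluation examples use the central `window_snps` SNPs of
#' each simulated region, avoiding edge effects of tract placement.
#'
#' @inheritParams encode_alignment
#' @return a (2, H, window_snps) array, or NULL if the region has fewer than
#'   `window_snps` segregating sites.
#' @export
encode_central_window <- function(aln, H = 44L, window_snps = 128L,
                                  seed = 1L) {
  s <- ncol(aln$mat)
  if (s < window_snps) return(NULL)
  start <- (s - window_snps) %/% 2L + 1L
  cols <- start:(start + window_snps - 1L)
  sub <- polarize(aln$mat[, cols, drop = FALSE])
  assemble_tensor(
    upsample(sub[pop_rows(aln, 1L), , drop = FALSE], H,
             derive_seed(seed, paste0(aln$chrom, "/central/p1"))),
    upsample(sub[pop_rows(aln, 2L), , drop = FALSE], H,
             derive_seed(seed, paste0(aln$chrom, "/central/p2"))))
}
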