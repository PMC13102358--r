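# Genomic-landscape statistics: nucleotide diversity, telomere distance,
# gene overlap, random-window nulls, and effect-size comparisons.

#' Nucleotide diversity of a window
#'
#' Unbiased per-site heterozygosity averaged per bp over the window span:
#' pi = sum_s 2 p_s (1 - p_s) n/(n-1) / span.
#'
#' @param mat haplotypes x sites 0/1 matrix (n >= 2 haplotypes); allele
#'   labelling is irrelevant (p and 1-p are symmetric).
#' @param span_bp window length in bp (> 0).
#' @return per-bp nucleotide diversity.
#' @export
nucleotide_diversity <- function(mat, span_bp) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  stopifnot(n >= 2)
  if (span_bp <= 0) stop("window span must be positive")
  if (ncol(mat) == 0L) return(0)
  p <- colMeans(mat)
  sum(2 * p * (1 - p)) * n / (n - 1) / span_bp
}

#' Distance from a window to the closest telomere
#'
#' @param start,end window bp span (0-based half-open).
#' @param chrom_length chromosome length in bp.
#' @return min(start, chrom_length - end).
#' @export
telomere_distance <- function(start, end, chrom_length) {
  if (any(start < 0) || any(end > chrom_length) || any(end < start)) {
    stop("window out of chromosome bounds")
  }
  pmin(start, chrom_length - end)
}

#' Base-pair overlap of a window with gene annotations
#'
#' Overlapping gene intervals are flattened to their union first, so bases
#' under several genes count once.
#'
#' @param start,end window bp span (0-based half-open).
#' @param genes data.frame with `start`, `end` columns (0-based half-open);
#'   optionally `chrom` (filter with `chrom =`).
#' @param chrom chromosome of the window, when `genes` spans several.
#' @return overlap in bp.
#' @export
gene_overlap <- function(start, end, genes, chrom = NULL) {
  if (!is.null(chrom) && !is.null(genes$chrom)) {
    genes <- genes[genes$chrom == chrom, , drop = FALSE]
  }
  if (nrow(genes) == 0L) return(0)
  g <- IRanges::reduce(IRanges::IRanges(start = genes$start + 1,
                                        end = genes$end))
  w <- IRanges::IRanges(start = start + 1, end = end)
  sum(IRanges::width(GenomicRanges::intersect(g, w)))
}

#' Random-window null datasets
#'
#' Generates `replicates` datasets of windows with exactly the observed
#' multiset of lengths, each placed uniformly along the genome (chromosome
#' chosen proportional to its feasible placement range, start uniform).
#' Windows may overlap each other and any annotation, mirroring unrestricted
#' random placement.
#'
#' @param lengths observed region lengths (bp).
#' @param chrom_lengths named chromosome lengths.
#' @param replicates number of null datasets (default 100).
#' @param seed integer seed.
#' @return list of data.frames (chrom, bp_start, bp_end), one per replicate.
#' @export
random_null <- function(lengths, chrom_lengths, replicates = 100L, seed = 1L) {
  stopifnot(length(lengths) >= 1L, !is.null(names(chrom_lengths)))
  if (max(lengths) > max(chrom_lengths)) {
    stop("a region is longer than every chromosome")
  }
  chroms <- names(chrom_lengths)
  with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      out <- lapply(lengths, function(len) {
        ok <- chrom_lengths >= len
        pr <- ifelse(ok, chrom_lengths, 0) # chromosome chosen ~ length
        ch <- sample(chroms, 1L, prob = pr)
        s <- floor(runif(1L, 0, chrom_lengths[[ch]] - len + 1))
        data.frame(chrom = ch, bp_start = s, bp_end = s + len,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    })
  })
}

#' Cohen's d (pooled standard deviation)
#'
#' @param x,y numeric groups.
#' @return standardized mean difference (x minus y).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Compare observed vs null window statistics on the log scale
#'
#' Both groups are natural-log transformed (to approximate normality); zeros
#' are replaced by half the smallest positive value in the pooled data before
#' transformation. A two-tailed Welch t-test and Cohen's d (pooled SD) are
#' computed on the transformed values. The effect size is oriented observed
#' minus null: positive Cd means the observed group is larger.
#'
#' @param observed,null numeric vectors of per-window statistics.
#' @return a `comparison_result` list: `cd`, `p_value`, `mean_observed`,
#'   `mean_null` (raw-scale means), `n`.
#' @export
compare_groups <- function(observed, null) {
  stopifnot(length(observed) >= 2L, length(null) >= 2L,
            all(observed >= 0), all(null >= 0))
  pooled <- c(observed, null)
  pos <- pooled[pooled > 0]
  if (length(pos) == 0L) stop("all values are zero")
  floor_val <- min(pos) / 2
  lo <- log(pmax(observed, floor_val))
  ln <- log(pmax(null, floor_val))
  if (stats::sd(lo) == 0 && stats::sd(ln) == 0) {
    if (isTRUE(all.equal(mean(lo), mean(ln)))) {
      return(structure(list(cd = 0, p_value = 1,
                            mean_observed = mean(observed),
                            mean_null = mean(null),
                            n = c(length(observed), length(null))),
                       class = "comparison_result"))
    }
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(lo, ln, alternative = "two.sided", var.equal = FALSE)
  structure(list(cd = cohens_d(lo, ln), p_value = tt$p.value,
                 mean_observed = mean(observed), mean_null = mean(null),
                 n = c(length(observed), length(null))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Cd = %.3f, p = %.3g (obs mean %.4g vs null mean %.4g)\n",
              x$cd, x$p_value, x$mean_observed, x$mean_null))
  invisible(x)
}

#' Pearson correlation between per-chromosome fractions and lengths
#'
#' @param fractions per-chromosome introgressed fractions.
#' @param lengths chromosome lengths, same order.
#' @return list(r, p_value, n).
#' @export
chromosome_correlation <- function(fractions, lengths) {
  stopifnot(length(fractions) == length(lengths), length(fractions) >= 3L)
  if (stats::sd(fractions) == 0 || stats::sd(lengths) == 0) {
    stop("zero variance; correlation undefined")
  }
  ct <- stats::cor.test(fractions, lengths, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(fractions))
}

#' Window statistics for a set of regions
#'
#' Computes nucleotide diversity (from a cohort alignment), telomere
#' distance, and gene overlap for each region.
#'
#' @param regions data.frame chrom/bp_start/bp_end.
#' @param alignments named list of [haplotype_alignment()] per chromosome
#'   (or NULL to skip diversity).
#' @param chrom_lengths named chromosome lengths.
#' @param genes gene annotation data.frame (chrom/start/end) or NULL.
#' @param population 1, 2 or "both": haplotype rows used for diversity.
#' @return data.frame with pi, telomere_distance, gene_overlap per region.
#' @export
window_stats <- function(regions, alignments, chrom_lengths, genes = NULL,
                         population = "both") {
  n <- nrow(regions)
  pi_v <- rep(NA_real_, n)
  td <- numeric(n)
  go <- numeric(n)
  for (i in seq_len(n)) {
    ch <- regions$chrom[i]
    s <- regions$bp_start[i]
    e <- regions$bp_end[i]
    td[i] <- telomere_distance(s, e, chrom_lengths[[ch]])
    go[i] <- if (is.null(genes)) 0 else gene_overlap(s, e, genes, chrom = ch)
    if (!is.null(alignments) && ch %in% names(alignments)) {
      aln <- alignments[[ch]]
      rows <- switch(as.character(population),
                     "1" = pop_rows(aln, 1L), "2" = pop_rows(aln, 2L),
                     seq_len(nrow(aln$mat)))
      inwin <- aln$positions >= s & aln$positions < e
      pi_v[i] <- nucleotide_diversity(
        aln$mat[rows, inwin, drop = FALSE], span_bp = e - s)
    }
  }
  cbind(regions, data.frame(pi = pi_v, telomere_distance = td,
                            gene_overlap = go))
}
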