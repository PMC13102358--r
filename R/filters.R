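# Site-level and window-level variant filters producing the analysis-ready
# and demography-ready SNP sets.
#
# Coordinates are 0-based half-open internally; the VCF layer converts its
# 1-based positions on the way in and out. BED masks are native 0-based.

#' Filter configuration with the study's default thresholds
#'
#' @param fs_max drop sites with phred-scaled strand bias FS >= this (60).
#' @param mq_min drop sites with mapping quality MQ <= this (40).
#' @param qd_min drop sites with quality-by-depth QD < this (6; stricter than
#'   the GATK-suggested 2).
#' @param missing_max_fraction per-population missingness threshold (0.15,
#'   drop at >= threshold).
#' @param depth_window_bp depth tile width (10 kbp).
#' @param depth_mode_multiplier exclude windows with population depth sum
#'   above this multiple of the mode (1.5).
#' @param thin_bp minimum spacing for demography-prep thinning (50 kbp).
#' @return a `filter_config`.
#' @export
filter_config <- function(fs_max = 60, mq_min = 40, qd_min = 6,
                          missing_max_fraction = 0.15,
                          depth_window_bp = 10000,
                          depth_mode_multiplier = 1.5,
                          thin_bp = 50000) {
  stopifnot(fs_max > 0, mq_min > 0, qd_min > 0,
            missing_max_fraction > 0, missing_max_fraction < 1,
            depth_window_bp > 0, depth_mode_multiplier > 0, thin_bp > 0)
  structure(list(fs_max = fs_max, mq_min = mq_min, qd_min = qd_min,
                 missing_max_fraction = missing_max_fraction,
                 depth_window_bp = depth_window_bp,
                 depth_mode_multiplier = depth_mode_multiplier,
                 thin_bp = thin_bp),
            class = "filter_config")
}

#' Site-level quality filter
#'
#' A site is dropped iff it is not a biallelic SNP, falls in the repeat mask,
#' or fails a quality rule (FS >= fs_max, MQ <= mq_min, QD < qd_min). Absent
#' annotation values (NA) never fail a rule, matching permissive behavior on
#' missing fields. The reason codes the first failing rule in the order
#' above.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `biallelic`
#'   (logical), and optional `FS`, `MQ`, `QD` (NA allowed).
#' @param config a [filter_config()].
#' @param repeat_mask data.frame chrom/start/end (0-based half-open) or NULL.
#' @return data.frame with `keep` (logical) and `reason` (NA when kept).
#' @export
filter_site <- function(sites, config = filter_config(), repeat_mask = NULL) {
  n <- nrow(sites)
  getcol <- function(nm) {
    if (is.null(sites[[nm]])) rep(NA_real_, n) else sites[[nm]]
  }
  fs <- getcol("FS")
  mq <- getcol("MQ")
  qd <- getcol("QD")
  masked <- rep(FALSE, n)
  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0L) {
    gr <- GenomicRanges::GRanges(
      repeat_mask$chrom,
      IRanges::IRanges(start = repeat_mask$start + 1, end = repeat_mask$end))
    pts <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(start = sites$pos + 1, width = 1))
    masked[S4Vectors::queryHits(IRanges::findOverlaps(pts, gr))] <- TRUE
  }
  reason <- rep(NA_character_, n)
  reason[!is.na(qd) & qd < config$qd_min] <- "QD"
  reason[!is.na(mq) & mq <= config$mq_min] <- "MQ"
  reason[!is.na(fs) & fs >= config$fs_max] <- "FS"
  reason[masked] <- "repeat_mask"
  reason[!sites$biallelic] <- "not_biallelic"
  data.frame(keep = is.na(reason), reason = reason, stringsAsFactors = FALSE)
}

#' Per-population missingness filter
#'
#' Drops a site when the fraction of missing genotype calls within the
#' population reaches the threshold (default 15%).
#'
#' @param missing_counts missing genotype calls per site (integer vector), or
#'   a logical matrix (individuals x sites) of missingness.
#' @param n_individuals population size (required with a count vector).
#' @param missing_max_fraction threshold (default 0.15).
#' @return logical keep vector.
#' @export
missingness_filter <- function(missing_counts, n_individuals = NULL,
                               missing_max_fraction = 0.15) {
  if (is.matrix(missing_counts)) {
    n_individuals <- nrow(missing_counts)
    missing_counts <- colSums(missing_counts)
  }
  if (is.null(n_individuals) || n_individuals <= 0) {
    stop("population must contain at least one individual")
  }
  missing_counts / n_individuals < missing_max_fraction
}

.binned_mode <- function(x) {
  # deterministic mode on integer-rounded values; ties -> smallest value
  r <- round(x)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)]) # which.max takes the first = smallest
}

#' Collapsed-paralog depth filter on fixed windows
#'
#' Excludes any 10-kbp tile whose per-population depth sum exceeds
#' `multiplier` times the mode of the tile-sum distribution (mode computed on
#' values rounded to integers; ties broken to the smallest modal value). A
#' window at or below the mode is never excluded.
#'
#' @param window_sums numeric vector of per-window population depth sums.
#' @param multiplier threshold multiple of the mode (default 1.5).
#' @return logical vector, TRUE = excluded.
#' @export
depth_window_filter <- function(window_sums, multiplier = 1.5) {
  stopifnot(all(window_sums >= 0))
  if (all(window_sums == 0)) {
    stop("all depth sums are zero; mode is degenerate")
  }
  m <- .binned_mode(window_sums)
  window_sums > multiplier * m
}

#' Thin sites to a minimum physical spacing
#'
#' Greedy left-to-right scan: the first site is kept, and each later site is
#' kept iff it lies at least `thin_bp` from the last kept site (">=", the
#' vcftools convention).
#'
#' @param positions sorted ascending bp positions (one chromosome).
#' @param thin_bp minimum spacing (default 50,000).
#' @return the retained positions.
#' @export
thin_sites <- function(positions, thin_bp = 50000) {
  if (length(positions) == 0L) return(positions)
  if (is.unsorted(positions, strictly = FALSE)) {
    stop("positions must be sorted ascending")
  }
  keep <- logical(length(positions))
  keep[1L] <- TRUE
  last <- positions[1L]
  for (i in seq_along(positions)[-1L]) {
    if (positions[i] - last >= thin_bp) {
      keep[i] <- TRUE
      last <- positions[i]
    }
  }
  positions[keep]
}

#' Exclude positions inside annotated genes
#'
#' Intervals are 0-based half-open, so a position equal to an interval's end
#' coordinate is retained.
#'
#' @param positions 0-based bp positions.
#' @param genes data.frame with `start`, `end` (0-based half-open), sorted.
#' @return positions not covered by any gene interval.
#' @export
exclude_genic <- function(positions, genes) {
  if (is.null(genes) || nrow(genes) == 0L) return(positions)
  g <- IRanges::IRanges(start = genes$start + 1, end = genes$end)
  pts <- IRanges::IRanges(start = positions + 1, width = 1)
  hit <- S4Vectors::queryHits(IRanges::findOverlaps(pts, g))
  if (length(hit) == 0L) return(positions)
  positions[-unique(hit)]
}

#' Tabulate per-window depth sums from a depth profile table
#'
#' @param depth data.frame with columns individual, chrom, win_start, depth.
#' @param individuals subset of individuals forming the population.
#' @return data.frame chrom, win_start, sum.
#' @export
depth_window_sums <- function(depth, individuals = NULL) {
  dt <- data.table::as.data.table(depth)
  if (!is.null(individuals)) dt <- dt[dt$individual %in% individuals, ]
  out <- dt[, list(sum = sum(depth)), by = c("chrom", "win_start")]
  as.data.frame(out)
}

#' Apply the full site-level filter stack to a parsed cohort VCF
#'
#' Composes [filter_site()], the per-population [missingness_filter()], and
#' the per-population [depth_window_filter()]; writes an optional
#' tab-separated report (site, verdict, reason).
#'
#' @param vcf parsed cohort (see [read_cohort_vcf()]).
#' @param pop_sizes diploid individuals per population.
#' @param config a [filter_config()].
#' @param repeat_mask repeat annotation data.frame or NULL.
#' @param depth depth profile table or NULL to skip the depth rule.
#' @param report_path optional TSV report path.
#' @return logical keep vector over VCF rows, with a `reason` attribute.
#' @export
filter_cohort_sites <- function(vcf, pop_sizes, config = filter_config(),
                                repeat_mask = NULL, depth = NULL,
                                report_path = NULL) {
  sites <- vcf$sites
  res <- filter_site(sites, config, repeat_mask)
  reason <- res$reason
  # per-population missingness on the genotype matrix (NA = missing call)
  p1 <- seq_len(pop_sizes[1])
  p2 <- pop_sizes[1] + seq_len(pop_sizes[2])
  for (rows in list(p1, p2)) {
    miss <- colSums(is.na(vcf$gt1[rows, , drop = FALSE]))
    keep <- missingness_filter(miss, length(rows),
                               config$missing_max_fraction)
    reason[is.na(reason) & !keep] <- "missingness"
  }
  if (!is.null(depth)) {
    ind_pops <- list(p1, p2)
    for (k in 1:2) {
      sums <- depth_window_sums(depth, individuals = ind_pops[[k]])
      excl <- depth_window_filter(sums$sum, config$depth_mode_multiplier)
      bad <- sums[excl, , drop = FALSE]
      if (nrow(bad) > 0L) {
        win <- paste(sites$chrom,
                     (sites$pos %/% config$depth_window_bp) *
                       config$depth_window_bp)
        hit <- win %in% paste(bad$chrom, bad$win_start)
        reason[is.na(reason) & hit] <- "depth_window"
      }
    }
  }
  keep <- is.na(reason)
  if (!is.null(report_path)) {
    data.table::fwrite(
      data.table::data.table(chrom = sites$chrom, pos = sites$pos,
                             verdict = ifelse(keep, "keep", "drop"),
                             reason = ifelse(keep, ".", reason)),
      report_path, sep = "\t")
  }
  attr(keep, "reason") <- reason
  keep
}
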