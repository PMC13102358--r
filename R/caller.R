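# Threshold decision rule, neighbor relaxation, merging, and cross-scan
# union accounting.

#' Caller configuration
#'
#' @param p primary probability threshold (default 0.9).
#' @param p_neighbor relaxed threshold for windows adjacent to called windows
#'   (default 0.7).
#' @return a `caller_config`.
#' @export
caller_config <- function(p = 0.9, p_neighbor = 0.7) {
  stopifnot(p > 0.5, p <= 1, p_neighbor > 0, p_neighbor <= p)
  structure(list(p = p, p_neighbor = p_neighbor), class = "caller_config")
}

#' Assign scenario classes from four-class probabilities
#'
#' A window is ELtoIL when p(ELtoIL) + p(BiDir) exceeds the threshold P (and
#' the symmetric ILtoEL sum does not), ILtoEL symmetrically, BiDir when both
#' summed probabilities exceed P, and none otherwise. The summed rule catches
#' windows whose unidirectional and bidirectional probabilities are
#' individually moderate but jointly strong evidence of gene flow.
#'
#' @param probs numeric(4) or an n x 4 matrix in [SCENARIO_CLASSES] order.
#' @param p probability threshold.
#' @return character vector of assigned classes.
#' @export
assign_class <- function(probs, p = 0.9) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  stopifnot(ncol(probs) == 4L, all(probs >= 0))
  sum_el <- probs[, 1L] + probs[, 3L] # ELtoIL + BiDir
  sum_il <- probs[, 2L] + probs[, 3L] # ILtoEL + BiDir
  el <- sum_el > p
  il <- sum_il > p
  out <- rep("none", nrow(probs))
  out[el & !il] <- "ELtoIL"
  out[il & !el] <- "ILtoEL"
  out[el & il] <- "BiDir"
  out
}

#' Build a window-call table from scan probabilities
#'
#' @param windows data.frame from [extract_windows()] (plus a `chrom`
#'   column, recycled if absent).
#' @param probs n x 4 probability matrix, rows aligned with `windows`.
#' @param chrom chromosome id used when `windows` lacks a `chrom` column.
#' @param config a [caller_config()].
#' @return data.frame of window calls: chrom, bp/SNP spans, the four
#'   probabilities, `class`, and `stage` ("primary" for threshold-P calls,
#'   "none" otherwise before extension).
#' @export
window_calls <- function(windows, probs, chrom = "chr1",
                         config = caller_config()) {
  stopifnot(nrow(windows) == nrow(probs))
  if (is.null(windows$chrom)) windows$chrom <- chrom
  cls <- assign_class(probs, config$p)
  out <- data.frame(chrom = windows$chrom,
                    bp_start = windows$bp_start, bp_end = windows$bp_end,
                    snp_start = windows$snp_start, snp_end = windows$snp_end,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(probs))
  names(out)[6:9] <- SCENARIO_CLASSES
  out$class <- cls
  out$stage <- ifelse(cls == "none", "none", "primary")
  out
}

#' Relax the threshold for windows adjacent to called windows
#'
#' Introgressed haplotypes often span several windows, so windows next to a
#' confident call get a more lenient threshold. Single non-iterative pass:
#' every none-window whose immediate predecessor or successor in the sliding
#' sequence (same chromosome) is a primary call is re-evaluated with
#' [assign_class()] at `p_neighbor`. Newly extended calls never seed further
#' extension, and primary calls are never changed.
#'
#' @param calls data.frame from [window_calls()], in genomic order per
#'   chromosome.
#' @param config a [caller_config()].
#' @return the updated call table; extended windows get stage
#'   "neighbor-extended".
#' @export
neighbor_extension <- function(calls, config = caller_config()) {
  if (nrow(calls) == 0L) return(calls)
  ord_ok <- all(tapply(calls$bp_start, calls$chrom,
                       function(x) !is.unsorted(x, strictly = FALSE)))
  if (!isTRUE(ord_ok)) stop("calls must be ordered by position per chromosome")
  primary <- calls$stage == "primary"
  same_chrom_prev <- c(FALSE, calls$chrom[-1L] == calls$chrom[-nrow(calls)])
  prev_primary <- c(FALSE, primary[-nrow(calls)]) & same_chrom_prev
  next_primary <- c(primary[-1L], FALSE) & c(same_chrom_prev[-1L], FALSE)
  candidate <- calls$class == "none" & (prev_primary | next_primary)
  if (any(candidate)) {
    probs <- as.matrix(calls[candidate, SCENARIO_CLASSES, drop = FALSE])
    new_cls <- assign_class(probs, config$p_neighbor)
    flipped <- new_cls != "none"
    idx <- which(candidate)[flipped]
    calls$class[idx] <- new_cls[flipped]
    calls$stage[idx] <- "neighbor-extended"
  }
  calls
}

#' Merge consecutive same-class window calls into regions
#'
#' Maximal runs of consecutive (overlapping or abutting in the sliding
#' sequence) windows of the same non-none class become one region whose bp
#' span is the union of the constituent windows. Runs break across
#' chromosomes, across classes, and at none-windows.
#'
#' @param calls ordered call table (after extension, if used).
#' @return data.frame of merged regions: chrom, bp_start, bp_end, class,
#'   n_windows.
#' @export
merge_calls <- function(calls) {
  keep <- calls$class != "none"
  empty <- data.frame(chrom = character(), bp_start = numeric(),
                      bp_end = numeric(), class = character(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  idx <- which(keep)
  brk <- c(TRUE,
           calls$chrom[idx[-1L]] != calls$chrom[idx[-length(idx)]] |
             calls$class[idx[-1L]] != calls$class[idx[-length(idx)]] |
             diff(idx) != 1L)
  run <- cumsum(brk)
  out <- lapply(split(idx, run), function(ii) {
    data.frame(chrom = calls$chrom[ii[1L]],
               bp_start = min(calls$bp_start[ii]),
               bp_end = max(calls$bp_end[ii]),
               class = calls$class[ii[1L]],
               n_windows = length(ii), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$bp_start + 1,
                                          end = regions$bp_end))
}

.flat_width <- function(regions) {
  if (nrow(regions) == 0L) return(0)
  sum(IRanges::width(IRanges::reduce(.regions_to_granges(regions))))
}

#' Genome fraction occupied by merged regions
#'
#' Regions of each class are flattened to their bp union before summing, so
#' overlapping windows are not double-counted; the overall fraction uses the
#' union over all non-none classes.
#'
#' @param regions data.frame from [merge_calls()] (bp coordinates 0-based
#'   half-open).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return list with `overall` fraction, per-`class` fractions, and
#'   `per_chromosome` (data.frame chrom, fraction over all classes).
#' @export
genome_fraction <- function(regions, chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)))
  if (nrow(regions) > 0L) {
    if (!all(regions$chrom %in% names(chrom_lengths))) {
      stop("region on unknown chromosome")
    }
    if (any(regions$bp_end > chrom_lengths[regions$chrom] |
              regions$bp_start < 0)) {
      stop("region out of chromosome bounds")
    }
  }
  total <- sum(chrom_lengths)
  per_class <- vapply(setdiff(SCENARIO_CLASSES, "none"), function(cl) {
    .flat_width(regions[regions$class == cl, , drop = FALSE]) / total
  }, 0)
  per_chrom <- vapply(names(chrom_lengths), function(ch) {
    .flat_width(regions[regions$chrom == ch, , drop = FALSE]) /
      chrom_lengths[[ch]]
  }, 0)
  list(overall = .flat_width(regions) / total,
       per_class = per_class,
       per_chromosome = data.frame(chrom = names(chrom_lengths),
                                   length = as.numeric(chrom_lengths),
                                   fraction = as.numeric(per_chrom),
                                   stringsAsFactors = FALSE))
}

#' Partition two scans' regions into exclusive and shared fractions
#'
#' Splits the bp union of regions from two scans (e.g. the two population
#' pairs) into three disjoint interval sets: detected only in A, only in B,
#' and in both. Fractions are relative to total genome length, so
#' A-only + B-only + both equals the union fraction exactly.
#'
#' @param regions_a,regions_b merged-region tables.
#' @param chrom_lengths named chromosome lengths.
#' @return list with `fractions` (a_only, b_only, both, union) and the three
#'   `GRanges` interval sets.
#' @export
union_scans <- function(regions_a, regions_b, chrom_lengths) {
  total <- sum(chrom_lengths)
  ga <- IRanges::reduce(.regions_to_granges(regions_a))
  gb <- IRanges::reduce(.regions_to_granges(regions_b))
  both <- GenomicRanges::intersect(ga, gb)
  a_only <- GenomicRanges::setdiff(ga, gb)
  b_only <- GenomicRanges::setdiff(gb, ga)
  w <- function(g) sum(as.numeric(IRanges::width(g)))
  fractions <- c(a_only = w(a_only) / total, b_only = w(b_only) / total,
                 both = w(both) / total,
                 union = w(GenomicRanges::union(ga, gb)) / total)
  list(fractions = fractions, a_only = a_only, b_only = b_only, both = both)
}

#' Write merged regions (or calls) as BED
#'
#' BED is 0-based half-open; region coordinates are written as-is with the
#' class (and probability, for calls) in the name/score columns.
#'
#' @param x region or call table with chrom/bp_start/bp_end/class.
#' @param path output path.
#' @export
write_regions_bed <- function(x, path) {
  df <- data.frame(chrom = x$chrom, start = format(x$bp_start, scientific = FALSE, trim = TRUE),
                   end = format(x$bp_end, scientific = FALSE, trim = TRUE),
                   name = x$class)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
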