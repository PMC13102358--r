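# Classifier performance measurement and joint-SFS comparison.

#' Confusion table over the four scenario classes
#'
#' @param truth,predicted character vectors of class labels.
#' @return a 4 x 4 contingency table (rows = true class, cols = predicted).
#' @export
confusion_table <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% SCENARIO_CLASSES),
            all(predicted %in% SCENARIO_CLASSES))
  table(factor(truth, SCENARIO_CLASSES), factor(predicted, SCENARIO_CLASSES),
        dnn = c("true", "predicted"))
}

.safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Precision and recall from a confusion table
#'
#' Precision is true positives over all cases called as a class; recall is
#' true positives over all cases simulated under that class. Binary presence
#' metrics collapse the three introgression classes against "none";
#' directionality metrics are computed only over windows where introgression
#' presence was correctly detected. Empty denominators yield NA (absent), not
#' 0 -- a class that is never called has no meaningful precision.
#'
#' @param tab a [confusion_table()].
#' @return a `metric_report` list: `per_class` (data.frame class, precision,
#'   recall), `presence` (precision, recall), `directionality` (data.frame).
#' @export
precision_recall <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(4L, 4L)), all(tab >= 0))
  per_class <- data.frame(
    class = SCENARIO_CLASSES,
    precision = vapply(1:4, function(i) .safe_ratio(tab[i, i], sum(tab[, i])), 0),
    recall = vapply(1:4, function(i) .safe_ratio(tab[i, i], sum(tab[i, ])), 0),
    stringsAsFactors = FALSE)
  intro <- 1:3
  tp <- sum(tab[intro, intro])
  presence <- list(
    precision = .safe_ratio(tp, sum(tab[, intro])),
    recall = .safe_ratio(tp, sum(tab[intro, ])))
  # directionality: restrict to correctly-detected-presence windows
  sub <- tab[intro, intro, drop = FALSE]
  directionality <- data.frame(
    class = SCENARIO_CLASSES[intro],
    precision = vapply(intro, function(i) .safe_ratio(sub[i, i], sum(sub[, i])), 0),
    recall = vapply(intro, function(i) .safe_ratio(sub[i, i], sum(sub[i, ])), 0),
    stringsAsFactors = FALSE)
  structure(list(per_class = per_class, presence = presence,
                 directionality = directionality),
            class = "metric_report")
}

#' Sweep the decision threshold over a labelled evaluation set
#'
#' @param probs n x 4 probability matrix from [predict_discriminator()].
#' @param truth true class labels.
#' @param p_values thresholds to evaluate (default the study's five values).
#' @return data.frame with one row per threshold: presence and per-direction
#'   precision/recall.
#' @export
evaluate_thresholds <- function(probs, truth,
                                p_values = c(0.75, 0.8, 0.85, 0.9, 0.95)) {
  out <- lapply(p_values, function(p) {
    rep_ <- precision_recall(confusion_table(truth, assign_class(probs, p)))
    data.frame(p = p,
               presence_precision = rep_$presence$precision,
               presence_recall = rep_$presence$recall,
               ELtoIL_precision = rep_$directionality$precision[1],
               ELtoIL_recall = rep_$directionality$recall[1],
               ILtoEL_precision = rep_$directionality$precision[2],
               ILtoEL_recall = rep_$directionality$recall[2],
               BiDir_precision = rep_$directionality$precision[3],
               BiDir_recall = rep_$directionality$recall[3])
  })
  do.call(rbind, out)
}

#' Build labelled evaluation sets across a sequencing-depth sweep
#'
#' One set per mean depth lambda; all individuals are corrupted at
#' heterozygous sites through the allelic-dropout model, emulating low
#' coverage (wrong homozygote calls).
#'
#' @param model a [demographic_model()].
#' @param per_scenario simulations per scenario class.
#' @param lambdas mean depths (default 2:6).
#' @param seed master seed; the underlying genealogies are shared across
#'   depths so sets differ only in error injection.
#' @param region_bp region length per simulation.
#' @param samples optional diploid sample counts.
#' @return named list (by lambda) of lists with `examples` (corrupted),
#'   `labels`.
#' @export
build_depth_sweep_sets <- function(model, per_scenario, lambdas = 2:6,
                                   seed = 1L, region_bp = 1.1e6,
                                   samples = NULL) {
  stopifnot(all(lambdas >= 1))
  labels <- rep(SCENARIO_CLASSES, per_scenario)
  specs <- with_seed(derive_seed(seed, "depth-specs"),
                     lapply(labels, draw_scenario))
  base <- simulate_examples(model, specs, region_bp = region_bp, seed = seed,
                            samples = samples)
  out <- lapply(lambdas, function(lam) {
    cfg <- depth_error_config(lambda = lam)
    ex <- lapply(seq_along(base), function(i) {
      e <- base[[i]]
      e$alignment <- inject_depth_errors(
        e$alignment, cfg, seed = derive_seed(seed, sprintf("err%d", i)))
      e
    })
    list(lambda = lam, examples = ex, labels = labels)
  })
  names(out) <- paste0("lambda", lambdas)
  out
}

#' Build the "realistic" evaluation set
#'
#' Emulates the real cohort: only a designated number of low-depth
#' individuals per population is corrupted (mean depth 4x by default), and
#' each region's mutation and recombination rates share a mean-1
#' Gamma(alpha, 1/alpha) scaling factor.
#'
#' @param model a [demographic_model()].
#' @param per_scenario simulations per scenario class.
#' @param low_depth integer(2): corrupted individuals per population.
#' @param lambda mean depth for corrupted individuals (default 4).
#' @param heterogeneity a [rate_heterogeneity_config()] or NULL to disable.
#' @param seed master seed.
#' @param region_bp region length per simulation.
#' @param samples optional diploid sample counts per population.
#' @return list with `examples`, `labels`, `rate_scales`.
#' @export
build_realistic_set <- function(model, per_scenario, low_depth = c(12L, 12L),
                                lambda = 4, heterogeneity = rate_heterogeneity_config(),
                                seed = 1L, region_bp = 1.1e6, samples = NULL) {
  if (is.null(samples)) samples <- .default_samples(model)
  stopifnot(length(low_depth) == 2L, all(low_depth >= 0),
            all(low_depth <= samples))
  labels <- rep(SCENARIO_CLASSES, per_scenario)
  specs <- with_seed(derive_seed(seed, "realistic-specs"),
                     lapply(labels, draw_scenario))
  base <- simulate_examples(model, specs, region_bp = region_bp, seed = seed,
                            samples = samples, heterogeneity = heterogeneity)
  cfg <- depth_error_config(lambda = lambda)
  # designated low-depth individuals: the first low_depth[k] of population k
  inds <- c(seq_len(low_depth[1]),
            if (low_depth[2] > 0) samples[1] + seq_len(low_depth[2]))
  ex <- lapply(seq_along(base), function(i) {
    e <- base[[i]]
    if (length(inds)) {
      e$alignment <- inject_depth_errors(
        e$alignment, cfg, individuals = inds,
        seed = derive_seed(seed, sprintf("rerr%d", i)))
    }
    e
  })
  list(examples = ex, labels = labels,
       rate_scales = vapply(base, `[[`, 0, "rate_scale"))
}

#' Predict scenario classes for a list of labelled examples
#'
#' Encodes each example's central window and applies the discriminator.
#'
#' @param net a trained `discriminator`.
#' @param examples list of `labelled_example`s.
#' @param H padded haplotype dimension.
#' @param seed encoding seed.
#' @return n x 4 probability matrix.
#' @export
predict_examples <- function(net, examples, H = 44L, seed = 1L) {
  W <- net$input_shape[3]
  tens <- array(0, dim = c(2L, H, W, length(examples)))
  for (i in seq_along(examples)) {
    tw <- encode_central_window(examples[[i]]$alignment, H = H,
                                window_snps = W,
                                seed = derive_seed(seed, paste0("pe", i)))
    if (is.null(tw)) stop("example ", i, " has fewer than ", W, " sites")
    tens[, , , i] <- tw
  }
  predict_discriminator(net, tens)
}

# ---------------------------------------------------------------------------
# Joint site frequency spectrum

#' Two-population joint site frequency spectrum
#'
#' Counts segregating sites by allele count in each population. Observed
#' windows carry no outgroup, so the default `"minor"` polarization folds by
#' the joint major allele, matching the tensor encoding. Simulated
#' alignments come derived-coded straight from the coalescent engine (allele
#' 1 = derived), so `polarization = "derived"` yields the unfolded spectrum
#' used when comparing against training simulations; opposite-frequency
#' shared variation (cells near the (0, n2) and (n1, 0) corners) is only
#' visible on that scale. Cell (i+1, j+1) counts sites with allele-1 count i
#' in population 1 and j in population 2.
#'
#' @param aln a [haplotype_alignment()] (or a 0/1 matrix plus `pop_sizes`,
#'   taken as already coded).
#' @param pop_sizes haplotype counts; taken from the alignment when omitted.
#' @param polarization `"minor"` (fold by joint majority) or `"derived"`
#'   (use the coding as-is).
#' @return an (n1+1) x (n2+1) integer matrix with a `mask` attribute marking
#'   the two fixed corners (0,0) and (n1,n2).
#' @export
joint_sfs <- function(aln, pop_sizes = NULL,
                      polarization = c("minor", "derived")) {
  polarization <- match.arg(polarization)
  if (inherits(aln, "haplotype_alignment")) {
    pop_sizes <- aln$pop_sizes
    mat <- if (polarization == "minor") polarize(aln$mat) else aln$mat
  } else {
    stopifnot(!is.null(pop_sizes))
    mat <- as.matrix(aln)
    if (polarization == "minor") mat <- polarize(mat)
  }
  n1 <- pop_sizes[1]
  n2 <- pop_sizes[2]
  c1 <- colSums(mat[seq_len(n1), , drop = FALSE])
  c2 <- colSums(mat[n1 + seq_len(n2), , drop = FALSE])
  if (any(c1 > n1) || any(c2 > n2)) stop("allele count exceeds sample size")
  sfs <- matrix(0L, n1 + 1L, n2 + 1L)
  for (k in seq_along(c1)) {
    sfs[c1[k] + 1L, c2[k] + 1L] <- sfs[c1[k] + 1L, c2[k] + 1L] + 1L
  }
  mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  mask[1L, 1L] <- TRUE
  mask[n1 + 1L, n2 + 1L] <- TRUE
  attr(sfs, "mask") <- mask
  sfs
}

#' Opposite-frequency shared-variation mass of a joint SFS
#'
#' Sums the cells adjacent to the (0, n2) and (n1, 0) corners: sites at high
#' frequency in one population and low in the other, the signature enriched
#' by introgression.
#'
#' @param sfs matrix from [joint_sfs()].
#' @param k corner neighborhood size (default 3 cells per axis).
#' @return fraction of (unmasked) sites in the two corner neighborhoods.
#' @export
opposite_frequency_mass <- function(sfs, k = 3L) {
  n1 <- nrow(sfs) - 1L
  n2 <- ncol(sfs) - 1L
  mask <- attr(sfs, "mask")
  tot <- sum(sfs[!mask])
  if (tot == 0) return(0)
  rows_hi <- (n1 + 1L - k + 1L):(n1 + 1L)
  cols_hi <- (n2 + 1L - k + 1L):(n2 + 1L)
  m <- sum(sfs[rows_hi, 1:k]) + sum(sfs[1:k, cols_hi])
  m / tot
}

#' Poisson composite log-likelihood of a data SFS under a model SFS
#'
#' The model spectrum is rescaled by the optimal factor
#' theta = sum(data)/sum(model) over unmasked cells, then the Poisson
#' log-likelihood sum(d * log(theta*m) - theta*m - log Gamma(d+1)) is
#' computed; masked cells (fixed corners by default) are ignored. Scaling
#' the model by any positive constant leaves the result unchanged.
#'
#' @param data,model same-shape SFS matrices.
#' @param mask logical matrix of cells to exclude; defaults to the `mask`
#'   attribute of `data`, or the two fixed corners.
#' @return the composite log-likelihood (scalar). -Inf with a warning when
#'   the model is zero where the data is not.
#' @export
ll_multinom <- function(data, model, mask = NULL) {
  stopifnot(all(dim(data) == dim(model)))
  if (is.null(mask)) mask <- attr(data, "mask")
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(data), ncol(data))
    mask[1L, 1L] <- TRUE
    mask[nrow(data), ncol(data)] <- TRUE
  }
  d <- as.numeric(data[!mask])
  m <- as.numeric(model[!mask])
  if (any(m < 0) || any(d < 0)) stop("negative SFS entries")
  if (any(m == 0 & d > 0)) {
    warning("model SFS is zero where data is nonzero; -Inf likelihood")
    return(-Inf)
  }
  theta <- sum(d) / sum(m)
  use <- m > 0
  sum(d[use] * log(theta * m[use]) - theta * m[use] - lgamma(d[use] + 1)) -
    sum(theta * m[!use])
}

#' Write a metric report to JSON
#' @param report data.frame or `metric_report`.
#' @param path output path.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
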