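# End-to-end orchestration: simulate -> train -> scan -> evaluate -> stats,
# with per-stage manifests and a reproducible master seed.

#' Assemble a run configuration
#'
#' Layered defaults: every parameter has a package default, overridable here
#' (and again by CLI flags). Stage parameters mirror the individual module
#' configurations.
#'
#' @param out_dir run output directory.
#' @param pair population pair ("ILa-ELw" or "ILa-ELs").
#' @param model_index fixture model index (1..3).
#' @param seed master seed for every stage.
#' @param cohort a [cohort_config()] (default derives from `seed`).
#' @param scenario_mix cohort scenario mix.
#' @param per_scenario training simulations per scenario class.
#' @param region_bp simulated region length for training examples.
#' @param preset discriminator preset ("desk" or "paper").
#' @param train training overrides, a [train_config()].
#' @param caller a [caller_config()].
#' @param eval_per_scenario evaluation simulations per scenario class.
#' @param null_replicates random-null datasets for the stats stage.
#' @return a `run_config`.
#' @export
run_config <- function(out_dir, pair = "ILa-ELw", model_index = 1L,
                       seed = 1L, cohort = NULL,
                       scenario_mix = c(none = 0.70, ELtoIL = 0.15,
                                        ILtoEL = 0.10, BiDir = 0.05),
                       per_scenario = 200L, region_bp = 3e5,
                       preset = "desk", train = NULL,
                       caller = caller_config(),
                       eval_per_scenario = 50L, null_replicates = 100L) {
  if (is.null(cohort)) cohort <- cohort_config(seed = seed)
  if (is.null(train)) {
    train <- train_config(max_epochs = 4L, steps_per_epoch = 200L,
                          patience = 2L, seed = seed)
  }
  structure(list(out_dir = out_dir, pair = pair, model_index = model_index,
                 seed = seed, cohort = cohort, scenario_mix = scenario_mix,
                 per_scenario = per_scenario, region_bp = region_bp,
                 preset = preset, train = train, caller = caller,
                 eval_per_scenario = eval_per_scenario,
                 null_replicates = null_replicates),
            class = "run_config")
}

.stage_manifest <- function(dir, stage, seed, outputs) {
  frag <- list(stage = stage, seed = seed,
               package_version = as.character(utils::packageVersion("introscan")),
               outputs = lapply(outputs, function(p) {
                 list(path = p, md5 = unname(tools::md5sum(p)))
               }))
  path <- file.path(dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(frag, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Validate a run's manifest chain
#'
#' Re-hashes every output recorded by the stage manifests.
#'
#' @param out_dir run directory.
#' @return TRUE when every recorded md5 matches; otherwise an error naming
#'   the first mismatching file.
#' @export
validate_manifest <- function(out_dir) {
  frs <- list.files(out_dir, "^manifest-.*\\.json$", full.names = TRUE)
  if (length(frs) == 0L) stop("no stage manifests found in ", out_dir)
  for (f in frs) {
    frag <- jsonlite::read_json(f, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    for (o in frag$outputs) {
      cur <- unname(tools::md5sum(o$path))
      if (!identical(cur, o$md5)) {
        stop("manifest mismatch for ", o$path, " (stage ", frag$stage, ")")
      }
    }
  }
  TRUE
}

#' Run the pipeline end to end (or a subset of stages)
#'
#' Stages: `synth` (generate the truth-annotated cohort), `simulate` (build
#' the labelled tensor store), `train` (fit the discriminator), `scan`
#' (window calls + merged regions + genome fractions on the cohort VCF),
#' `evaluate` (threshold sweep on fresh labelled simulations), `stats`
#' (landscape comparison of called regions vs random nulls). Later stages
#' resume from the on-disk artifacts of earlier ones.
#'
#' @param config a [run_config()].
#' @param stages character subset of the stage names, in any order.
#' @param verbose print stage timings.
#' @return named list of per-stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "simulate", "train", "scan",
                                    "evaluate", "stats"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- lynx_model(config$pair, config$model_index)
  res <- list()
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  cohort_dir <- file.path(config$out_dir, "cohort")
  store_dir <- file.path(config$out_dir, "tensors")
  ckpt <- file.path(config$out_dir, "checkpoint.rds")
  scan_dir <- file.path(config$out_dir, "scan")

  if ("synth" %in% stages) {
    t0 <- Sys.time()
    res$synth <- generate_cohort(config$cohort, model, config$scenario_mix,
                                 out_dir = cohort_dir)
    .stage_manifest(config$out_dir, "synth", config$cohort$seed,
                    res$synth$paths)
    say("synth: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    samples <- stats::setNames(config$cohort$individuals, model$populations)
    store <- build_training_set(
      list(model), config$per_scenario, store_dir,
      seed = derive_seed(config$seed, "training-set"),
      region_bp = config$region_bp, samples = samples,
      H = 2L * max(config$cohort$individuals))
    res$simulate <- manifest_summary(store)
    .stage_manifest(config$out_dir, "simulate", config$seed,
                    list(file.path(store_dir, "manifest.json")))
    say("simulate: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("train" %in% stages) {
    t0 <- Sys.time()
    if (!file.exists(file.path(store_dir, "manifest.json"))) {
      stop("train requires the 'simulate' stage outputs in ", store_dir)
    }
    store <- tensor_store_open(store_dir)
    net <- build_network(store$shape, config$preset,
                         seed = derive_seed(config$seed, "net-init"))
    fit <- train_discriminator(store, config$train, net = net)
    save_checkpoint(fit$net, ckpt)
    write_history(fit$history, file.path(config$out_dir, "history.csv"))
    res$train <- fit[c("history", "best_epoch")]
    .stage_manifest(config$out_dir, "train", config$train$seed,
                    list(ckpt, file.path(config$out_dir, "history.csv")))
    say("train: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("scan" %in% stages) {
    t0 <- Sys.time()
    if (!file.exists(ckpt)) stop("scan requires the 'train' stage checkpoint")
    if (!file.exists(file.path(cohort_dir, "cohort.vcf"))) {
      stop("scan requires the 'synth' stage cohort VCF")
    }
    net <- load_checkpoint(ckpt)
    res$scan <- scan_cohort(cohort_dir, net, config, scan_dir)
    .stage_manifest(config$out_dir, "scan", config$seed,
                    res$scan$paths)
    say("scan: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("evaluate" %in% stages) {
    t0 <- Sys.time()
    if (!file.exists(ckpt)) {
      stop("evaluate requires the 'train' stage checkpoint")
    }
    net <- load_checkpoint(ckpt)
    samples <- stats::setNames(config$cohort$individuals, model$populations)
    labels <- rep(SCENARIO_CLASSES, config$eval_per_scenario)
    eseed <- derive_seed(config$seed, "evaluate")
    specs <- with_seed(eseed, lapply(labels, draw_scenario))
    ex <- simulate_examples(model, specs, region_bp = config$region_bp,
                            seed = eseed, samples = samples)
    probs <- predict_examples(net, ex, H = net$input_shape[2], seed = eseed)
    sweep_tab <- evaluate_thresholds(probs, labels)
    mpath <- file.path(config$out_dir, "metrics.csv")
    utils::write.csv(sweep_tab, mpath, row.names = FALSE)
    res$evaluate <- sweep_tab
    .stage_manifest(config$out_dir, "evaluate", eseed, list(mpath))
    say("evaluate: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("stats" %in% stages) {
    t0 <- Sys.time()
    regions_path <- file.path(scan_dir, "regions.bed")
    if (!file.exists(regions_path)) {
      stop("stats requires the 'scan' stage regions in ", scan_dir)
    }
    res$stats <- landscape_report(cohort_dir, scan_dir, config)
    .stage_manifest(config$out_dir, "stats", config$seed,
                    list(file.path(config$out_dir, "landscape.json")))
    say("stats: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  }
  invisible(res)
}

#' Scan a cohort VCF for introgressed windows
#'
#' Reads the phased VCF, encodes sliding windows per chromosome, applies the
#' discriminator, the threshold rule with neighbor relaxation, and merging.
#'
#' @param cohort_dir directory with cohort.vcf and chrom_lengths.tsv.
#' @param net a trained `discriminator`.
#' @param config a [run_config()] (caller thresholds, seed).
#' @param out_dir scan output directory.
#' @return list: `calls`, `regions`, `fractions`, `paths`.
#' @export
scan_cohort <- function(cohort_dir, net, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- read_cohort_vcf(file.path(cohort_dir, "cohort.vcf"))
  cl <- data.table::fread(file.path(cohort_dir, "chrom_lengths.tsv"),
                          data.table = FALSE)
  chrom_lengths <- stats::setNames(as.numeric(cl$length), cl$chrom)
  pops <- unique(sub("_[0-9]+$", "", vcf$sample_names))
  pop_sizes <- as.integer(table(factor(sub("_[0-9]+$", "", vcf$sample_names),
                                       levels = pops)))
  alns <- phased_alignments(vcf, pop_sizes, populations = pops)
  H <- net$input_shape[2]
  all_calls <- list()
  for (ch in names(alns)) {
    enc <- encode_alignment(alns[[ch]], H = H,
                            window_snps = net$input_shape[3],
                            seed = derive_seed(config$seed, "scan"))
    if (nrow(enc$windows) == 0L) next
    probs <- predict_discriminator(net, enc$tensors)
    calls <- window_calls(enc$windows, probs, chrom = ch, config$caller)
    all_calls[[ch]] <- neighbor_extension(calls, config$caller)
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  regions <- merge_calls(calls)
  fractions <- genome_fraction(regions, chrom_lengths)
  paths <- list(calls = file.path(out_dir, "calls.bed"),
                regions = file.path(out_dir, "regions.bed"),
                fractions = file.path(out_dir, "fractions.json"))
  write_regions_bed(calls[calls$class != "none", , drop = FALSE],
                    paths$calls)
  write_regions_bed(regions, paths$regions)
  jsonlite::write_json(fractions, paths$fractions, auto_unbox = TRUE,
                       digits = NA)
  list(calls = calls, regions = regions, fractions = fractions,
       paths = paths)
}

#' Landscape comparison of called regions vs a random-window null
#'
#' @param cohort_dir cohort artifact directory.
#' @param scan_dir scan artifact directory (regions.bed).
#' @param config a [run_config()].
#' @return list of `comparison_result`s per statistic plus the chromosome
#'   length correlation; written to `<out_dir>/landscape.json`.
#' @export
landscape_report <- function(cohort_dir, scan_dir, config) {
  regions <- read_bed(file.path(scan_dir, "regions.bed"))
  names(regions) <- c("chrom", "bp_start", "bp_end")
  cl <- data.table::fread(file.path(cohort_dir, "chrom_lengths.tsv"),
                          data.table = FALSE)
  chrom_lengths <- stats::setNames(as.numeric(cl$length), cl$chrom)
  genes <- read_bed(file.path(cohort_dir, "genes.bed"))
  vcf <- read_cohort_vcf(file.path(cohort_dir, "cohort.vcf"))
  pops <- unique(sub("_[0-9]+$", "", vcf$sample_names))
  pop_sizes <- as.integer(table(factor(sub("_[0-9]+$", "", vcf$sample_names),
                                       levels = pops)))
  alns <- phased_alignments(vcf, pop_sizes, populations = pops)
  if (nrow(regions) == 0L) stop("no called regions; nothing to compare")
  obs <- window_stats(regions, alns, chrom_lengths, genes)
  nulls <- random_null(regions$bp_end - regions$bp_start, chrom_lengths,
                       replicates = config$null_replicates,
                       seed = derive_seed(config$seed, "null"))
  null_stats <- do.call(rbind, lapply(nulls, window_stats, alignments = alns,
                                      chrom_lengths = chrom_lengths,
                                      genes = genes))
  out <- list(
    pi = unclass(compare_groups(obs$pi, null_stats$pi)),
    telomere_distance = unclass(compare_groups(obs$telomere_distance,
                                               null_stats$telomere_distance)),
    gene_overlap = unclass(compare_groups(obs$gene_overlap,
                                          null_stats$gene_overlap)))
  cls <- data.frame(chrom = names(chrom_lengths),
                    length = as.numeric(chrom_lengths))
  regs <- regions
  regs$class <- "ELtoIL" # correlation uses all called bp regardless of class
  fr <- genome_fraction(regs, chrom_lengths)
  if (nrow(fr$per_chromosome) >= 3L &&
        stats::sd(fr$per_chromosome$fraction) > 0) {
    out$chromosome_correlation <- chromosome_correlation(
      fr$per_chromosome$fraction, fr$per_chromosome$length)
  }
  jsonlite::write_json(out, file.path(dirname(scan_dir), "landscape.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  out
}
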