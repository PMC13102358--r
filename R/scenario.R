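# Labelled scenario simulation: mass-migration pulses, rate heterogeneity,
# genotyping-error injection, and training-set assembly.

#' Construct a scenario specification
#'
#' @param label one of the four scenario classes.
#' @param pulses list of pulses, each `list(recipient=, donor=, proportion=,
#'   time=)` with recipient/donor in {1, 2} (population index).
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(label, pulses = list()) {
  label <- match.arg(label, SCENARIO_CLASSES)
  if (label == "none" && length(pulses) > 0L) {
    stop("label 'none' implies no pulses")
  }
  if (label == "ELtoIL" &&
      !(length(pulses) == 1L && pulses[[1L]]$recipient == 1L)) {
    stop("ELtoIL requires exactly one pulse into population 1 (Iberian side)")
  }
  if (label == "ILtoEL" &&
      !(length(pulses) == 1L && pulses[[1L]]$recipient == 2L)) {
    stop("ILtoEL requires exactly one pulse into population 2")
  }
  if (label == "BiDir") {
    recips <- sort(vapply(pulses, `[[`, 0L, "recipient"))
    if (!identical(recips, c(1L, 2L))) {
      stop("BiDir requires one pulse per direction")
    }
  }
  for (p in pulses) {
    stopifnot(p$proportion >= 0.05, p$proportion <= 0.50,
              p$time >= 1, p$time <= 5000)
  }
  structure(list(label = label, pulses = pulses), class = "scenario_spec")
}

.draw_pulse <- function(recipient) {
  list(recipient = recipient, donor = if (recipient == 1L) 2L else 1L,
       proportion = runif(1L, 0.05, 0.50),
       time = runif(1L, 1, 5000))
}

#' Draw a random scenario specification for a class label
#'
#' Pulse proportions are uniform on [0.05, 0.50] (fraction of lineages moved)
#' and pulse times uniform on [1, 5000] generations before present;
#' bidirectional scenarios draw the two directions independently.
#'
#' @param label scenario class.
#' @return a [scenario_spec()].
#' @export
draw_scenario <- function(label = SCENARIO_CLASSES) {
  label <- match.arg(label)
  pulses <- switch(label,
    none = list(),
    ELtoIL = list(.draw_pulse(1L)),
    ILtoEL = list(.draw_pulse(2L)),
    BiDir = list(.draw_pulse(1L), .draw_pulse(2L))
  )
  scenario_spec(label, pulses)
}

#' Rate-heterogeneity configuration
#'
#' Mean-1 gamma scaling of the baseline mutation and recombination rates:
#' shape `alpha`, scale `1/alpha`.
#'
#' @param alpha gamma shape (default 10).
#' @return a `rate_heterogeneity_config`.
#' @export
rate_heterogeneity_config <- function(alpha = 10) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha, scale = 1 / alpha),
            class = "rate_heterogeneity_config")
}

#' Sample a shared mutation/recombination rate scaling factor
#'
#' @param config a [rate_heterogeneity_config()].
#' @param n number of draws.
#' @return positive factors with mean 1 and variance `1/alpha`.
#' @export
sample_rate_scaler <- function(config = rate_heterogeneity_config(), n = 1L) {
  stopifnot(inherits(config, "rate_heterogeneity_config"))
  rgamma(n, shape = config$alpha, scale = config$scale)
}

#' Depth-based genotyping-error configuration
#'
#' @param lambda mean sequencing depth (Poisson mean, > 0).
#' @param min_depth minimum enforced depth (default 1 read).
#' @param p_allele per-read probability of drawing either allele at a
#'   heterozygous site (default 0.5).
#' @return a `depth_error_config`.
#' @export
depth_error_config <- function(lambda, min_depth = 1L, p_allele = 0.5) {
  stopifnot(lambda > 0, min_depth >= 1)
  structure(list(lambda = lambda, min_depth = as.integer(min_depth),
                 p_allele = p_allele),
            class = "depth_error_config")
}

#' Inject allelic-dropout genotyping errors at heterozygous sites
#'
#' For each designated diploid individual and each heterozygous site, a read
#' depth `d = max(min_depth, Poisson(lambda))` is drawn and reads assigned to
#' the two alleles by binomial sampling. Sites where only one allele is
#' observed become homozygous for it (both haplotypes re-phased to the called
#' allele); sites showing both alleles stay heterozygous. Homozygous sites
#' are never altered.
#'
#' @param aln a [haplotype_alignment()] with raw (ref/alt) coding. Individual
#'   k occupies haplotype rows 2k-1 and 2k.
#' @param config a [depth_error_config()].
#' @param individuals integer indices of diploid individuals to corrupt
#'   (default all).
#' @param seed integer seed.
#' @return the corrupted alignment; attribute `n_changed` counts altered
#'   genotype calls.
#' @export
inject_depth_errors <- function(aln, config, individuals = NULL, seed = 1L) {
  stopifnot(inherits(aln, "haplotype_alignment"),
            inherits(config, "depth_error_config"))
  n_ind <- nrow(aln$mat) %/% 2L
  if (is.null(individuals)) individuals <- seq_len(n_ind)
  stopifnot(all(individuals >= 1L), all(individuals <= n_ind))
  mat <- aln$mat
  changed <- 0L
  with_seed(seed, {
    for (k in sort(individuals)) {
      h1 <- mat[2L * k - 1L, ]
      h2 <- mat[2L * k, ]
      het <- which(h1 != h2)
      if (length(het) == 0L) next
      d <- pmax(config$min_depth, rpois(length(het), config$lambda))
      alt_reads <- rbinom(length(het), d, config$p_allele)
      to_ref <- het[alt_reads == 0L]
      to_alt <- het[alt_reads == d]
      mat[2L * k - 1L, to_ref] <- 0L
      mat[2L * k, to_ref] <- 0L
      mat[2L * k - 1L, to_alt] <- 1L
      mat[2L * k, to_alt] <- 1L
      changed <- changed + length(to_ref) + length(to_alt)
    }
  })
  aln$mat <- mat
  attr(aln, "n_changed") <- changed
  aln
}

.pulse_to_job <- function(spec, populations) {
  lapply(spec$pulses, function(p) {
    list(recipient = populations[p$recipient], donor = populations[p$donor],
         proportion = p$proportion, time = p$time)
  })
}

.default_samples <- function(model) {
  n2 <- if (identical(model$pair, "ILa-ELs")) 12L else 20L
  stats::setNames(c(22L, n2), model$populations)
}

#' Simulate one labelled example
#'
#' Runs a coalescent simulation of `region_bp` under the model, with the
#' scenario's mass-migration pulses. Replicates are re-simulated (bounded
#' attempts) until at least `min_sites` biallelic segregating sites exist and
#' every pulse left at least one recipient haplotype carrying donor ancestry
#' (verified via the engine's migrant-ancestry records).
#'
#' @param model a [demographic_model()].
#' @param spec a [scenario_spec()].
#' @param region_bp simulated region length (default 1.1 Mbp).
#' @param seed integer seed.
#' @param heterogeneity optional [rate_heterogeneity_config()]; when given, a
#'   shared gamma factor scales both mutation and recombination rates.
#' @param samples named diploid counts per population (defaults to the study
#'   design for the model's pair).
#' @param min_sites minimum segregating sites (default 128).
#' @param max_attempts resimulation bound (default 100).
#' @return a `labelled_example`: `spec`, `alignment`, `flags` (0/1 introgressed
#'   indicator per haplotype), `tracts`, `rate_scale`.
#' @export
simulate_example <- function(model, spec, region_bp = 1.1e6, seed = 1L,
                             heterogeneity = NULL, samples = NULL,
                             min_sites = 128L, max_attempts = 100L) {
  res <- simulate_examples(model, list(spec), region_bp, seed, heterogeneity,
                           samples, min_sites, max_attempts)
  res[[1L]]
}

#' Simulate a batch of labelled examples
#'
#' Vectorized form of [simulate_example()]: one engine invocation for the
#' whole batch.
#'
#' @inheritParams simulate_example
#' @param specs list of [scenario_spec()] objects.
#' @return list of `labelled_example`s, in input order.
#' @export
simulate_examples <- function(model, specs, region_bp = 1.1e6, seed = 1L,
                              heterogeneity = NULL, samples = NULL,
                              min_sites = 128L, max_attempts = 100L) {
  stopifnot(inherits(model, "demographic_model"), length(specs) >= 1L)
  if (is.null(samples)) samples <- .default_samples(model)
  config <- to_simulator_config(model)
  scales <- if (is.null(heterogeneity)) {
    rep(1, length(specs))
  } else {
    with_seed(derive_seed(seed, "rate-scalers"),
              sample_rate_scaler(heterogeneity, length(specs)))
  }
  reps <- lapply(seq_along(specs), function(i) {
    list(id = i - 1L,
         seed = derive_seed(seed, paste0("sim", i)),
         length = region_bp,
         rate_scale = scales[i],
         pulses = .pulse_to_job(specs[[i]], model$populations),
         min_sites = min_sites,
         require_tracts = TRUE,
         max_attempts = max_attempts)
  })
  out <- run_coalescent_batch(config, samples, reps)
  lapply(seq_along(specs), function(i) {
    r <- out[[i]]
    aln <- haplotype_alignment(r$mat, r$positions, r$pop_sizes,
                               chrom = paste0("sim", i),
                               populations = model$populations)
    structure(list(spec = specs[[i]], alignment = aln, flags = r$flags,
                   tracts = r$tracts, rate_scale = scales[i],
                   attempts = r$attempts),
              class = "labelled_example")
  })
}

# ---------------------------------------------------------------------------
# Tensor store: flat binary array container + JSON manifest. One byte per
# tensor entry (entries are binary), tensors stored sample-major in R array
# column-major order, shape (2, H, W).

#' Create an on-disk tensor store
#' @param dir directory to create.
#' @param shape integer(3) tensor shape, e.g. c(2, 44, 128).
#' @param class_order class labels in canonical order.
#' @return a `tensor_store` handle.
#' @export
tensor_store_create <- function(dir, shape, class_order = SCENARIO_CLASSES) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  store <- structure(list(dir = dir, shape = as.integer(shape),
                          class_order = class_order,
                          bin = file.path(dir, "tensors.bin"),
                          manifest = file.path(dir, "manifest.json")),
                     class = "tensor_store")
  if (file.exists(store$bin)) unlink(store$bin)
  store
}

#' Append tensors and their labels to a store
#' @param store a `tensor_store`.
#' @param tensors array of shape `c(shape, n)` (or a single tensor).
#' @param records data.frame with one row per tensor; must contain a `label`
#'   column; other columns (model id, seed, validation flag) are kept.
#' @return the store, invisibly.
#' @export
tensor_store_append <- function(store, tensors, records) {
  stopifnot(inherits(store, "tensor_store"))
  d <- dim(tensors)
  if (length(d) == 3L) {
    dim(tensors) <- c(d, 1L)
    d <- dim(tensors)
  }
  stopifnot(identical(d[1:3], store$shape), nrow(records) == d[4L],
            all(records$label %in% store$class_order))
  con <- file(store$bin, open = "ab")
  on.exit(close(con))
  writeBin(as.raw(as.integer(tensors)), con)
  old <- .store_records(store)
  new <- rbind(old, as.data.frame(records))
  jsonlite::write_json(
    list(version = 1L, shape = store$shape, n = nrow(new),
         class_order = store$class_order, records = new),
    store$manifest, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(store)
}

.store_records <- function(store) {
  if (!file.exists(store$manifest)) {
    return(data.frame(label = character()))
  }
  m <- jsonlite::read_json(store$manifest, simplifyVector = TRUE)
  as.data.frame(m$records, stringsAsFactors = FALSE)
}

#' Open an existing tensor store
#' @param dir store directory.
#' @return a `tensor_store` handle with `$records` populated.
#' @export
tensor_store_open <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  structure(list(dir = dir, shape = as.integer(m$shape),
                 class_order = m$class_order,
                 bin = file.path(dir, "tensors.bin"),
                 manifest = manifest,
                 n = m$n,
                 records = as.data.frame(m$records, stringsAsFactors = FALSE)),
            class = "tensor_store")
}

#' Read tensors from a store
#' @param store an opened `tensor_store`.
#' @param indices 1-based tensor indices (default all).
#' @return array of shape `c(shape, length(indices))`, double 0/1.
#' @export
tensor_store_read <- function(store, indices = NULL) {
  recs <- if (!is.null(store$records)) store$records else .store_records(store)
  n <- nrow(recs)
  if (is.null(indices)) indices <- seq_len(n)
  stopifnot(all(indices >= 1L), all(indices <= n))
  size <- prod(store$shape)
  out <- array(0, dim = c(store$shape, length(indices)))
  con <- file(store$bin, open = "rb")
  on.exit(close(con))
  for (j in seq_along(indices)) {
    seek(con, (indices[j] - 1L) * size)
    out[, , , j] <- as.integer(readBin(con, "raw", size))
  }
  out
}

#' Read a store's tensors as a raw-byte matrix
#'
#' One column per tensor, one byte per entry; avoids materializing large
#' training sets as doubles (the trainer converts per minibatch).
#'
#' @param store an opened `tensor_store`.
#' @return a raw matrix of dimension (prod(shape), n).
#' @export
tensor_store_read_raw <- function(store) {
  size <- prod(store$shape)
  recs <- if (!is.null(store$records)) store$records else .store_records(store)
  n <- nrow(recs)
  con <- file(store$bin, open = "rb")
  on.exit(close(con))
  x <- readBin(con, "raw", size * n)
  if (length(x) != size * n) stop("tensor store is truncated")
  dim(x) <- c(size, n)
  x
}

#' Build a labelled training set of window tensors
#'
#' Simulates `per_scenario` regions for each of the four scenario classes
#' under each model, encodes the central 128-SNP window of each region, and
#' writes the tensors plus a manifest (labels, model ids, seeds, stratified
#' validation split) to a tensor store. The full-scale profile of the study
#' is 12,000 simulations per scenario per model across three models (144,000
#' tensors); desk-scale runs use the same code path with smaller counts.
#'
#' @param models list of [demographic_model()]s.
#' @param per_scenario simulations per scenario class per model.
#' @param dir output store directory.
#' @param seed master seed.
#' @param region_bp simulated region length (default 1.1 Mbp).
#' @param H padded haplotype dimension (default 44).
#' @param window_snps SNPs per tensor window (default 128).
#' @param validation_fraction stratified validation fraction (default 0.05,
#'   rounded up per class so tiny runs keep a non-empty validation split).
#' @param samples optional named diploid counts per population.
#' @param heterogeneity optional [rate_heterogeneity_config()] (training
#'   defaults to fixed baseline rates).
#' @param batch_size simulations per engine invocation.
#' @return the `tensor_store`, with `$records` populated.
#' @export
build_training_set <- function(models, per_scenario, dir, seed = 1L,
                               region_bp = 1.1e6, H = 44L,
                               window_snps = 128L,
                               validation_fraction = 0.05,
                               samples = NULL, heterogeneity = NULL,
                               batch_size = 250L) {
  stopifnot(per_scenario > 0, length(models) >= 1L)
  if (inherits(models, "demographic_model")) models <- list(models)
  store <- tensor_store_create(dir, c(2L, H, window_snps))
  n_val <- ceiling(validation_fraction * per_scenario)
  for (m in seq_along(models)) {
    model <- models[[m]]
    for (label in SCENARIO_CLASSES) {
      done <- 0L
      while (done < per_scenario) {
        nb <- min(batch_size, per_scenario - done)
        bseed <- derive_seed(seed, sprintf("m%d/%s/b%d", m, label, done))
        specs <- with_seed(bseed, replicate(nb, draw_scenario(label),
                                            simplify = FALSE))
        ex <- simulate_examples(models[[m]], specs, region_bp = region_bp,
                                seed = bseed, samples = samples,
                                heterogeneity = heterogeneity,
                                min_sites = window_snps)
        tensors <- array(0, dim = c(2L, H, window_snps, nb))
        for (i in seq_len(nb)) {
          tensors[, , , i] <- encode_central_window(
            ex[[i]]$alignment, H = H, window_snps = window_snps,
            seed = derive_seed(bseed, paste0("enc", i)))
        }
        idx <- done + seq_len(nb)
        records <- data.frame(label = label, model = m, seed = bseed,
                              validation = idx > (per_scenario - n_val))
        tensor_store_append(store, tensors, records)
        done <- done + nb
      }
    }
  }
  tensor_store_open(dir)
}

#' Summarize a training-set manifest
#'
#' @param store an opened `tensor_store`.
#' @return list with `total`, per-(model, label) `counts` table, and
#'   per-label `validation` counts.
#' @export
manifest_summary <- function(store) {
  recs <- store$records
  list(total = nrow(recs),
       counts = table(model = recs$model, label = recs$label),
       validation = table(label = recs$label[recs$validation]))
}
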