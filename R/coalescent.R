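# R side of the coalescent simulation bridge.
#
# Ancestral-recombination-graph simulation is delegated to msprime (Python),
# driven in batches through a single subprocess call per batch: R writes a
# JSON job, the worker writes one JSON line per replicate. Everything above
# the ARG (demography event lists, pulse draws, acceptance of replicates,
# encoding) lives in R.

.python_bin <- function() {
  bin <- getOption("introscan.python", Sys.getenv("INTROSCAN_PYTHON", ""))
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) stop("no python interpreter found; the coalescent ",
                         "backend requires python with msprime")
  bin
}

.worker_script <- function() {
  p <- system.file("python", "coalesce.py", package = "introscan")
  if (!nzchar(p)) stop("bundled coalesce.py not found")
  p
}

.backend_checked <- new.env(parent = emptyenv())

#' Check that the msprime coalescent backend is available
#'
#' @param error error (default) or return FALSE when unavailable.
#' @return TRUE invisibly when available.
#' @export
check_simulation_backend <- function(error = TRUE) {
  if (isTRUE(.backend_checked$ok)) return(invisible(TRUE))
  bin <- tryCatch(.python_bin(), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(bin)) {
    out <- suppressWarnings(system2(bin, c("-c", shQuote("import msprime")),
                                    stdout = TRUE, stderr = TRUE))
    ok <- is.null(attr(out, "status"))
  }
  if (!ok && error) {
    stop("python with msprime is required for coalescent simulation; ",
         "set options(introscan.python=...) if it is not on the PATH")
  }
  .backend_checked$ok <- ok
  invisible(ok)
}

#' Run a batch of coalescent replicates
#'
#' Low-level entry point used by [simulate_example()], [generate_cohort()]
#' and the evaluation-set builders.
#'
#' @param config a `simulator_config` from [to_simulator_config()].
#' @param samples named integer vector of diploid sample counts per
#'   population, in (population 1, population 2) order.
#' @param replicates list of replicate descriptors, each with `id`, `seed`,
#'   `length`, and optionally `pulses` (list of
#'   `list(recipient=, donor=, proportion=, time=)`), `rate_scale`,
#'   `min_sites`, `require_tracts`, `max_attempts`.
#' @return a list (in replicate order) of simulation results:
#'   `positions` (integer bp), `mat` (haplotypes x sites 0/1 matrix, rows
#'   population 1 then population 2), `flags` (0/1 per haplotype),
#'   `tracts` (data.frame hap/left/right/donor), `pop_sizes`, `attempts`.
#' @export
run_coalescent_batch <- function(config, samples, replicates) {
  stopifnot(inherits(config, "simulator_config"), length(samples) == 2L,
            !is.null(names(samples)), length(replicates) >= 1L)
  check_simulation_backend()
  job <- list(
    demography = list(populations = config$populations,
                      migration = config$migration,
                      events = config$events),
    samples = as.list(as.integer(samples)),
    mutation_rate = config$mutation_rate,
    recombination_rate = config$recombination_rate,
    replicates = replicates
  )
  names(job$samples) <- names(samples)
  job_file <- tempfile("introscan-job-", fileext = ".json")
  out_file <- tempfile("introscan-out-", fileext = ".ndjson")
  on.exit(unlink(c(job_file, out_file)), add = TRUE)
  jsonlite::write_json(job, job_file, auto_unbox = TRUE, digits = NA)
  status <- system2(.python_bin(), c(.worker_script(), job_file, out_file),
                    stdout = "", stderr = "")
  if (!identical(status, 0L)) {
    stop("coalescent worker failed with status ", status)
  }
  lines <- readLines(out_file)
  if (length(lines) != 3L * length(replicates)) {
    stop("coalescent worker returned ", length(lines), " lines for ",
         length(replicates), " replicates")
  }
  lapply(seq_along(replicates), function(i) {
    .parse_sim_record(lines[3L * i - 2L], lines[3L * i - 1L], lines[3L * i])
  })
}

# worker record: JSON metadata line, space-separated positions line, and all
# haplotype rows as one concatenated 0/1 string (row-major)
.parse_sim_record <- function(meta_line, pos_line, hap_line) {
  x <- jsonlite::fromJSON(meta_line, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE)
  n_hap <- x$n_hap
  n_site <- x$n_site
  positions <- if (n_site > 0) {
    as.integer(strsplit(pos_line, " ", fixed = TRUE)[[1L]])
  } else {
    integer()
  }
  mat <- matrix(0L, nrow = n_hap, ncol = n_site)
  if (n_site > 0L) {
    mat <- matrix(utf8ToInt(hap_line) - 48L, nrow = n_hap, ncol = n_site,
                  byrow = TRUE)
  }
  tracts <- x$tracts
  if (is.null(tracts) || length(tracts) == 0L ||
      (is.data.frame(tracts) && nrow(tracts) == 0L)) {
    tracts <- data.frame(hap = integer(), left = numeric(),
                         right = numeric(), donor = character(),
                         origin = character())
  } else {
    tracts <- as.data.frame(tracts)
    tracts$hap <- as.integer(tracts$hap) + 1L # 1-based haplotype rows in R
  }
  list(id = x$id, attempts = x$attempts,
       positions = positions, mat = mat,
       flags = as.integer(x$flags), tracts = tracts,
       pop_sizes = as.integer(x$pop_sizes))
}
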