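# Truth-annotated synthetic cohorts: genome-scale phased VCF with known
# introgressed tracts, gene/repeat annotation tracks, per-individual depth
# profiles, and site-quality annotations.
#
# Internal coordinates are 0-based half-open; the VCF writer/reader converts
# to and from the 1-based VCF dialect.

#' Cohort configuration
#'
#' Defaults mirror the study design: 22 + 20 diploids (the ILa-ELw pair; use
#' `individuals = c(22, 12)` for ILa-ELs), 18 autosomes with a descending
#' length ladder so chromosome-length analyses have spread, ~4% missing
#' genotype calls, and a mix of high- and low-coverage individuals.
#'
#' @param individuals diploid individuals per population (default c(22, 20)).
#' @param n_chromosomes number of autosomes (default 18).
#' @param chromosome_lengths bp per chromosome (default a 20 -> 3 Mbp
#'   descending ladder of length `n_chromosomes`).
#' @param low_depth_individuals count of low-coverage individuals per
#'   population (default c(12, 12); they are the first individuals of each
#'   population block).
#' @param mean_depths named c(high=, low=) mean sequencing depths.
#' @param missing_rate per-genotype missing probability in the emitted VCF
#'   (phased analysis tensors are built from imputed data downstream).
#' @param seed master seed; all chromosome streams derive from it.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(individuals = c(22L, 20L), n_chromosomes = 18L,
                          chromosome_lengths = NULL,
                          low_depth_individuals = c(12L, 12L),
                          mean_depths = c(high = 25, low = 5),
                          missing_rate = 0.03, seed = 1L) {
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- round(seq(20e6, 3e6, length.out = n_chromosomes))
  }
  stopifnot(length(individuals) == 2L, all(individuals > 0),
            n_chromosomes > 0, length(chromosome_lengths) == n_chromosomes,
            all(chromosome_lengths > 0),
            all(low_depth_individuals >= 0),
            all(low_depth_individuals <= individuals),
            missing_rate >= 0, missing_rate < 1,
            all(mean_depths > 0))
  structure(list(individuals = as.integer(individuals),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_lengths = as.numeric(chromosome_lengths),
                 low_depth_individuals = as.integer(low_depth_individuals),
                 mean_depths = mean_depths,
                 missing_rate = missing_rate, seed = seed),
            class = "cohort_config")
}

.chrom_names <- function(config) paste0("chr", seq_len(config$n_chromosomes))

.sample_names <- function(config, populations = c("pop1", "pop2")) {
  c(sprintf("%s_%02d", populations[1], seq_len(config$individuals[1])),
    sprintf("%s_%02d", populations[2], seq_len(config$individuals[2])))
}

#' Generate gene and repeat annotation tracks
#'
#' Alternates intergenic gaps (exponential) and feature lengths (gamma, mean
#' ~20 kbp) along each chromosome, targeting a genome-wide bp density; for
#' genomes of 10 Mbp or more the realized density lands within ~10% of the
#' target by the law of large numbers.
#'
#' @param config a [cohort_config()].
#' @param gene_density target fraction of the genome under genes (0..1).
#' @param repeat_density target fraction under repeats.
#' @param seed seed (defaults to the config seed).
#' @return list of data.frames `genes`, `repeats` (chrom, start, end;
#'   0-based half-open, sorted, non-overlapping within a track).
#' @export
generate_annotations <- function(config, gene_density = 0.3,
                                 repeat_density = 0.3, seed = NULL) {
  stopifnot(gene_density >= 0, gene_density <= 1,
            repeat_density >= 0, repeat_density <= 1)
  if (is.null(seed)) seed <- config$seed
  track <- function(density, tag) {
    if (density == 0) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE))
    }
    mean_len <- 20000
    out <- list()
    for (ci in seq_len(config$n_chromosomes)) {
      L <- config$chromosome_lengths[ci]
      rows <- with_seed(derive_seed(seed, paste0(tag, "/chr", ci)), {
        pos <- 0
        starts <- ends <- numeric()
        repeat {
          gap <- if (density >= 1) 0 else rexp(1, rate = density /
                                                 (mean_len * (1 - density)))
          len <- rgamma(1, shape = 2, scale = mean_len / 2)
          s <- pos + gap
          e <- min(s + len, L)
          if (s >= L) break
          starts <- c(starts, floor(s))
          ends <- c(ends, ceiling(e))
          pos <- e
        }
        data.frame(chrom = .chrom_names(config)[ci], start = starts,
                   end = ends, stringsAsFactors = FALSE)
      })
      out[[ci]] <- rows
    }
    do.call(rbind, out)
  }
  list(genes = track(gene_density, "genes"),
       repeats = track(repeat_density, "repeats"))
}

.write_bed <- function(df, path) {
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  data.table::fwrite(
    data.frame(chrom = df$chrom,
               start = format(df$start, scientific = FALSE, trim = TRUE),
               end = format(df$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file
#' @param path BED path (0-based half-open).
#' @return data.frame chrom, start, end.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end"),
                          select = 1:3, data.table = FALSE)
  df
}

.random_bases <- function(n) {
  b <- c("A", "C", "G", "T")
  ref <- sample(b, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(b, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

.site_quality_annotations <- function(n) {
  fs <- round(rexp(n, rate = 1 / 8), 2)
  hi <- runif(n) < 0.015
  fs[hi] <- round(runif(sum(hi), 60, 200), 2)
  mq <- round(60 - rexp(n, rate = 1 / 2), 2)
  lo <- runif(n) < 0.015
  mq[lo] <- round(runif(sum(lo), 10, 40), 2)
  qd <- round(rgamma(n, shape = 6, scale = 2.5), 2)
  bad <- runif(n) < 0.02
  qd[bad] <- round(runif(sum(bad), 0, 5.99), 2)
  data.frame(FS = fs, MQ = mq, QD = qd)
}

#' Write a phased cohort VCF (4.2 dialect)
#'
#' One row per biallelic SNP with FS/MQ/QD INFO annotations and phased GT
#' calls; missing calls are written as `.|.`. Deterministic: identical input
#' yields a byte-identical file.
#'
#' @param alignments named list of [haplotype_alignment()] per chromosome.
#' @param info named list of per-chromosome data.frames (FS, MQ, QD).
#' @param missing named list of per-chromosome logical matrices
#'   (individuals x sites) marking masked genotype calls (or NULL).
#' @param alleles named list of per-chromosome list(ref=, alt=).
#' @param sample_names VCF sample column names.
#' @param chrom_lengths named chromosome lengths for the contig header.
#' @param path output path.
#' @export
write_cohort_vcf <- function(alignments, info, missing, alleles,
                             sample_names, chrom_lengths, path) {
  con <- file(path, open = "wb") # binary mode: fixed \n on every platform
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl("##fileformat=VCFv4.2")
  wl("##source=introscan-synthetic-cohort")
  for (ch in names(alignments)) {
    wl(sprintf("##contig=<ID=%s,length=%d>", ch,
               as.integer(chrom_lengths[[ch]])))
  }
  wl('##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled strand bias">')
  wl('##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">')
  wl('##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">')
  wl('##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">')
  wl(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT", sample_names), collapse = "\t"))
  for (ch in names(alignments)) {
    aln <- alignments[[ch]]
    s <- ncol(aln$mat)
    if (s == 0L) next
    n_ind <- nrow(aln$mat) %/% 2L
    a1 <- aln$mat[seq(1L, 2L * n_ind, by = 2L), , drop = FALSE]
    a2 <- aln$mat[seq(2L, 2L * n_ind, by = 2L), , drop = FALSE]
    gt <- matrix(paste(a1, a2, sep = "|"), nrow = n_ind)
    if (!is.null(missing) && !is.null(missing[[ch]])) {
      gt[missing[[ch]]] <- ".|."
    }
    inf <- info[[ch]]
    rows <- paste(ch, format(aln$positions + 1, scientific = FALSE,
                             trim = TRUE), ".",
                  alleles[[ch]]$ref, alleles[[ch]]$alt, ".", "PASS",
                  sprintf("FS=%s;MQ=%s;QD=%s", inf$FS, inf$MQ, inf$QD), "GT",
                  apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    wl(rows)
  }
  invisible(path)
}

#' Parse a phased cohort VCF
#'
#' Uses the Bioconductor VCF reader when available, with a light fallback
#' parser for the package's own dialect. Positions are converted to the
#' internal 0-based convention.
#'
#' @param path VCF path.
#' @return list: `sites` (chrom, pos, ref, alt, biallelic, FS, MQ, QD),
#'   `gt1`/`gt2` (individuals x sites allele matrices, NA = missing call),
#'   `sample_names`, `chrom_lengths`.
#' @export
read_cohort_vcf <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    v <- VariantAnnotation::readVcf(path, genome = "synthetic")
    rr <- SummarizedExperiment::rowRanges(v)
    rrdf <- as.data.frame(rr)
    alt <- as.character(S4Vectors::unstrsplit(
      IRanges::CharacterList(rr$ALT), sep = ","))
    inf <- VariantAnnotation::info(v)
    ref <- as.character(rr$REF)
    sites <- data.frame(
      chrom = as.character(rrdf$seqnames),
      pos = rrdf$start - 1,
      ref = ref, alt = alt,
      biallelic = !grepl(",", alt) & nchar(alt) == 1 & nchar(ref) == 1,
      FS = as.numeric(inf$FS), MQ = as.numeric(inf$MQ),
      QD = as.numeric(inf$QD), stringsAsFactors = FALSE)
    gt <- VariantAnnotation::geno(v)$GT # variants x samples
    sample_names <- colnames(gt)
    chrlen <- GenomeInfoDb::seqlengths(rr)
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    cn <- strsplit(sub("^#", "", hdr[length(hdr)]), "\t")[[1L]]
    tab <- data.table::fread(text = body, header = FALSE, sep = "\t",
                             col.names = cn, data.table = FALSE)
    getinfo <- function(s, key) {
      m <- regmatches(s, regexpr(paste0(key, "=[^;]+"), s))
      as.numeric(sub(paste0(key, "="), "", m))
    }
    sites <- data.frame(
      chrom = tab$CHROM, pos = tab$POS - 1, ref = tab$REF, alt = tab$ALT,
      biallelic = !grepl(",", tab$ALT) & nchar(tab$ALT) == 1 &
        nchar(tab$REF) == 1,
      FS = getinfo(tab$INFO, "FS"), MQ = getinfo(tab$INFO, "MQ"),
      QD = getinfo(tab$INFO, "QD"), stringsAsFactors = FALSE)
    gt <- as.matrix(tab[, -(1:9), drop = FALSE])
    sample_names <- cn[-(1:9)]
    ctg <- hdr[startsWith(hdr, "##contig")]
    chrlen <- stats::setNames(
      as.numeric(sub(".*length=(\\d+).*", "\\1", ctg)),
      sub(".*ID=([^,>]+).*", "\\1", ctg))
  }
  parse_allele <- function(ch) ifelse(ch %in% c("0", "1"),
                                      suppressWarnings(as.integer(ch)), NA_integer_)
  gt1 <- base::t(matrix(parse_allele(substr(gt, 1L, 1L)), nrow = nrow(gt)))
  gt2 <- base::t(matrix(parse_allele(substr(gt, 3L, 3L)), nrow = nrow(gt)))
  list(sites = sites, gt1 = gt1, gt2 = gt2, sample_names = sample_names,
       chrom_lengths = chrlen)
}

#' Build phased (imputed) haplotype alignments from a parsed VCF
#'
#' Missing calls are imputed to the site's major allele (ties to the
#' reference), mirroring the downstream assumption that phased inputs carry
#' no missing data.
#'
#' @param vcf output of [read_cohort_vcf()].
#' @param pop_sizes diploid individuals per population.
#' @param populations population labels.
#' @return named list of [haplotype_alignment()], one per chromosome present.
#' @export
phased_alignments <- function(vcf, pop_sizes,
                              populations = c("pop1", "pop2")) {
  n_ind <- sum(pop_sizes)
  stopifnot(nrow(vcf$gt1) == n_ind)
  out <- list()
  for (ch in unique(vcf$sites$chrom)) {
    cols <- which(vcf$sites$chrom == ch)
    h <- matrix(0L, nrow = 2L * n_ind, ncol = length(cols))
    h[seq(1L, 2L * n_ind, by = 2L), ] <- vcf$gt1[, cols, drop = FALSE]
    h[seq(2L, 2L * n_ind, by = 2L), ] <- vcf$gt2[, cols, drop = FALSE]
    if (anyNA(h)) {
      for (j in which(colSums(is.na(h)) > 0L)) {
        col <- h[, j]
        maj <- if (mean(col, na.rm = TRUE) > 0.5) 1L else 0L
        col[is.na(col)] <- maj
        h[, j] <- col
      }
    }
    out[[ch]] <- haplotype_alignment(
      h, vcf$sites$pos[cols], pop_sizes = 2L * pop_sizes, chrom = ch,
      populations = populations)
  }
  out
}

#' Fraction of haplotype-bp covered by tracts in a window
#'
#' Used to grade how much donor ancestry (pulse or background) a scan window
#' carries: 0 means genuinely gene-flow-free, small values mean a few
#' haplotype slivers.
#'
#' @param tracts hap-level tract table (chrom, left, right, hap).
#' @param chrom,start,end window coordinates (0-based half-open).
#' @param n_hap total haplotypes in the cohort.
#' @return covered haplotype-bp / (window length x n_hap).
#' @export
tract_coverage <- function(tracts, chrom, start, end, n_hap) {
  t2 <- tracts[tracts$chrom == chrom & tracts$left < end &
                 tracts$right > start, , drop = FALSE]
  if (nrow(t2) == 0L) return(0)
  sum(pmin(t2$right, end) - pmax(t2$left, start)) / ((end - start) * n_hap)
}

#' Generate a truth-annotated synthetic cohort
#'
#' Simulates every chromosome under the demographic model with a scenario
#' drawn from `scenario_mix`, records the resulting donor-ancestry tracts as
#' ground truth, injects per-genotype missingness (VCF only), and writes the
#' standard artifact set: phased VCF, gene and repeat BEDs, chromosome-length
#' table, per-individual 10-kbp depth table, and a truth JSON.
#'
#' @param config a [cohort_config()].
#' @param model a [demographic_model()].
#' @param scenario_mix named probabilities over [SCENARIO_CLASSES] (default
#'   70% none, 15% ELtoIL, 10% ILtoEL, 5% BiDir).
#' @param out_dir output directory (created).
#' @param gene_density,repeat_density annotation densities.
#' @param paralog_rate fraction of 10-kbp depth tiles emulating collapsed
#'   paralogs (depth multiplied across all individuals).
#' @return list with `paths` (vcf, genes, repeats, chrom_lengths, depth,
#'   truth), `truth` (pulse `tracts`/`hap_tracts`/`flags`, plus
#'   `background_tracts` from continuous migration so callers can separate
#'   genuinely gene-flow-free regions), `alignments` (uncorrupted, per
#'   chromosome), and `config`.
#' @export
generate_cohort <- function(config, model,
                            scenario_mix = c(none = 0.70, ELtoIL = 0.15,
                                             ILtoEL = 0.10, BiDir = 0.05),
                            out_dir, gene_density = 0.3,
                            repeat_density = 0.3, paralog_rate = 0.004) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(model, "demographic_model"),
            all(names(scenario_mix) %in% SCENARIO_CLASSES),
            abs(sum(scenario_mix) - 1) < 1e-8)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chroms <- .chrom_names(config)
  chrom_lengths <- stats::setNames(config$chromosome_lengths, chroms)
  seed <- config$seed
  samples <- stats::setNames(config$individuals, model$populations)

  # one scenario per chromosome, drawn from the mix
  labels <- with_seed(derive_seed(seed, "labels"), {
    sample(names(scenario_mix), config$n_chromosomes, replace = TRUE,
           prob = scenario_mix)
  })
  specs <- lapply(seq_along(labels), function(i) {
    with_seed(derive_seed(seed, paste0("spec/chr", i)),
              draw_scenario(labels[i]))
  })
  sim_cfg <- to_simulator_config(model)
  reps <- lapply(seq_along(chroms), function(i) {
    list(id = i - 1L, seed = derive_seed(seed, paste0("sim/chr", i)),
         length = chrom_lengths[[i]],
         pulses = .pulse_to_job(specs[[i]], model$populations),
         min_sites = 1L, require_tracts = length(specs[[i]]$pulses) > 0L,
         # continuous-migration donor tracts are recorded separately so
         # downstream "truth-free" checks can exclude background gene flow
         background_max_time = model$divergence_time,
         max_attempts = 50L)
  })
  sims <- run_coalescent_batch(sim_cfg, samples, reps)

  alignments <- list()
  info <- list()
  missing <- list()
  alleles <- list()
  flags <- list()
  hap_tracts <- list()
  n_ind <- sum(config$individuals)
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    r <- sims[[i]]
    if (ncol(r$mat) == 0L) {
      stop("chromosome ", ch, " has zero segregating sites")
    }
    alignments[[ch]] <- haplotype_alignment(
      r$mat, r$positions, r$pop_sizes, chrom = ch,
      populations = model$populations)
    s <- ncol(r$mat)
    info[[ch]] <- with_seed(derive_seed(seed, paste0("info/", ch)),
                            .site_quality_annotations(s))
    alleles[[ch]] <- with_seed(derive_seed(seed, paste0("alleles/", ch)),
                               .random_bases(s))
    missing[[ch]] <- with_seed(derive_seed(seed, paste0("miss/", ch)), {
      matrix(runif(n_ind * s) < config$missing_rate, nrow = n_ind)
    })
    flags[[ch]] <- r$flags
    if (nrow(r$tracts) > 0L) {
      tr <- r$tracts
      tr$chrom <- ch
      tr$recipient <- ifelse(tr$hap <= 2L * config$individuals[1],
                             model$populations[1], model$populations[2])
      hap_tracts[[ch]] <- tr
    }
  }
  all_tracts <- if (length(hap_tracts)) do.call(rbind, hap_tracts) else NULL
  background <- if (!is.null(all_tracts)) {
    all_tracts[all_tracts$origin == "background", , drop = FALSE]
  } else {
    NULL
  }
  hap_tracts <- lapply(hap_tracts, function(tr) {
    tr[tr$origin == "pulse", , drop = FALSE]
  })
  hap_tracts <- Filter(function(x) nrow(x) > 0L, hap_tracts)
  empty_tracts <- data.frame(hap = integer(), left = numeric(),
                             right = numeric(), donor = character(),
                             origin = character(), chrom = character(),
                             recipient = character(),
                             stringsAsFactors = FALSE)
  hap_tracts <- if (length(hap_tracts)) {
    do.call(rbind, hap_tracts)
  } else {
    empty_tracts
  }
  if (is.null(background)) background <- empty_tracts
  rownames(hap_tracts) <- NULL
  rownames(background) <- NULL
  # cohort-level truth tracts: bp union per (chromosome, recipient, donor)
  truth_tracts <- if (nrow(hap_tracts) > 0L) {
    parts <- split(hap_tracts,
                   paste(hap_tracts$chrom, hap_tracts$recipient,
                         hap_tracts$donor))
    out <- lapply(parts, function(p) {
      red <- IRanges::reduce(IRanges::IRanges(start = round(p$left) + 1,
                                              end = round(p$right)))
      data.frame(chrom = p$chrom[1L], bp_start = IRanges::start(red) - 1,
                 bp_end = IRanges::end(red), recipient = p$recipient[1L],
                 donor = p$donor[1L], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  } else {
    data.frame(chrom = character(), bp_start = numeric(), bp_end = numeric(),
               recipient = character(), donor = character(),
               stringsAsFactors = FALSE)
  }

  # depth profiles: per individual per 10-kbp tile, gamma noise around the
  # individual's mean; collapsed-paralog tiles multiply everyone's depth
  low <- c(seq_len(config$low_depth_individuals[1]),
           config$individuals[1] + seq_len(config$low_depth_individuals[2]))
  ind_means <- rep(config$mean_depths[["high"]], n_ind)
  ind_means[low] <- config$mean_depths[["low"]]
  depth <- list()
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    starts <- seq(0, chrom_lengths[[i]] - 1, by = 10000)
    depth[[ch]] <- with_seed(derive_seed(seed, paste0("depth/", ch)), {
      paralog <- runif(length(starts)) < paralog_rate
      d <- lapply(seq_len(n_ind), function(k) {
        dk <- rgamma(length(starts), shape = 20, scale = ind_means[k] / 20)
        dk[paralog] <- dk[paralog] * 2.5
        data.frame(individual = k, chrom = ch, win_start = starts,
                   depth = round(dk, 2))
      })
      do.call(rbind, d)
    })
  }
  depth <- do.call(rbind, depth)
  rownames(depth) <- NULL

  ann <- generate_annotations(config, gene_density, repeat_density,
                              seed = derive_seed(seed, "annotations"))

  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                genes = file.path(out_dir, "genes.bed"),
                repeats = file.path(out_dir, "repeats.bed"),
                chrom_lengths = file.path(out_dir, "chrom_lengths.tsv"),
                depth = file.path(out_dir, "depth.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_cohort_vcf(alignments, info, missing, alleles,
                   .sample_names(config, model$populations),
                   chrom_lengths, paths$vcf)
  .write_bed(ann$genes, paths$genes)
  .write_bed(ann$repeats, paths$repeats)
  data.table::fwrite(data.frame(chrom = chroms,
                                length = format(config$chromosome_lengths,
                                                scientific = FALSE,
                                                trim = TRUE)),
                     paths$chrom_lengths, sep = "\t")
  data.table::fwrite(depth, paths$depth, sep = "\t")
  truth <- list(tracts = truth_tracts, hap_tracts = hap_tracts,
                background_tracts = background,
                flags = flags, labels = stats::setNames(labels, chroms))
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  list(paths = paths, truth = truth, alignments = alignments,
       annotations = ann, depth = depth, config = config,
       chrom_lengths = chrom_lengths)
}
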