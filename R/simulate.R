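#' Simulation configuration for a pooled competition experiment
#'
#' Bundles the knobs of the forward simulator. Defaults mirror the pooled
#' M-factor screen: 5 mating--germination cycles, 3 biological replicates,
#' 75-bp single-end reads at a depth of at least 4x10^5 reads per sample,
#' and a between-cycle population bottleneck of ~1.5x10^7 cells
#' (10^5 cells per genotype at assembly).
#'
#' @param cycles Number of selection cycles (>= 1).
#' @param replicates Number of biological replicates (>= 1).
#' @param reads_per_sample Reads emitted per sequenced sample.
#' @param error_rate Per-base substitution error probability in \[0, 0.1\].
#' @param drift_cells Multinomial bottleneck size applied after each cycle;
#'   `NULL` for fully deterministic trajectories.
#' @param seed Root seed; every stochastic stage derives its own seed
#'   from it.
#' @param read_length Read length in bp (>= 30: the 6-nt anchor motif plus
#'   the 24-nt barcode must fit).
#' @param generations Vegetative generations per passage in the non-mating
#'   (rich medium) control regime.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(cycles = 5L, replicates = 3L,
                       reads_per_sample = 400000L, error_rate = 0.001,
                       drift_cells = 1.53e7, seed = 1L,
                       read_length = 75L, generations = 8L) {
  stopifnot(cycles >= 1, replicates >= 1, reads_per_sample >= 1,
            error_rate >= 0, error_rate <= 0.1,
            is.null(drift_cells) || drift_cells >= 1,
            generations >= 0)
  if (read_length < nchar(BARCODE_MOTIF) + BARCODE_LENGTH) {
    stop("read_length must be >= ", nchar(BARCODE_MOTIF) + BARCODE_LENGTH)
  }
  structure(list(cycles = as.integer(cycles),
                 replicates = as.integer(replicates),
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate,
                 drift_cells = drift_cells,
                 seed = as.integer(seed),
                 read_length = as.integer(read_length),
                 generations = as.integer(generations)),
            class = "sim_config")
}

#' One mating--germination selection cycle
#'
#' Selection is cell-autonomous: only mated cells survive the ethanol
#' treatment, so a genotype at frequency `f_i` with mating efficiency `m_i`
#' is propagated in proportion to `f_i * m_i`, renormalized.
#'
#' @param freqs Frequency vector summing to 1.
#' @param m Mating-efficiency vector in \[0, 1\], same length.
#' @return Updated frequency vector summing to 1.
#' @export
mating_cycle_update <- function(freqs, m) {
  .assert_frequencies(freqs)
  stopifnot(length(m) == length(freqs), all(m >= 0), all(m <= 1))
  total <- sum(freqs * m)
  if (total <= 0) stop("population extinct: no genotype mated this cycle")
  freqs * m / total
}

#' Vegetative serial-passage update (non-mating control regime)
#'
#' @param freqs Frequency vector summing to 1.
#' @param w Vegetative relative fitness per generation (> 0 entrywise).
#' @param generations Number of generations in the passage (>= 0).
#' @return Updated frequency vector `f_i' proportional to f_i * w_i^generations`.
#' @export
vegetative_passage_update <- function(freqs, w, generations) {
  .assert_frequencies(freqs)
  stopifnot(length(w) == length(freqs), all(w > 0), generations >= 0)
  x <- freqs * w^generations
  x / sum(x)
}

#' Forward-simulate a pooled competition across selection cycles
#'
#' Starts every genotype at equal frequency `1/N` and applies, per cycle,
#' the mating-selection update (when the condition is mating-permissive) or
#' the vegetative-passage update (the rich-medium control). When
#' `config$drift_cells` is set, frequencies are resampled multinomially
#' after each cycle to model the between-cycle population bottleneck;
#' with `drift_cells = NULL` trajectories are deterministic and equal the
#' closed form `f_i(T) = f_i(0) m_i^T / sum_j f_j(0) m_j^T`.
#'
#' @param library A `variant_library`.
#' @param profiles Named list of `fitness_profile`s covering the library.
#' @param cond A [condition()].
#' @param config A [sim_config()].
#' @return A `competition_run`: list with `trajectories` (one
#'   `(cycles + 1) x N` frequency matrix per replicate, rows
#'   `cycle0..cycleT`), `condition` and `config`.
#' @export
run_competition <- function(library, profiles, cond, config) {
  stopifnot(inherits(library, "variant_library"),
            inherits(cond, "assay_condition"),
            inherits(config, "sim_config"))
  ids <- library$variants$variant_id
  n <- length(ids)
  m <- efficiency_vector(profiles, library, cond$pH)
  w <- vegetative_vector(profiles, library)

  trajectories <- vector("list", config$replicates)
  for (rep_i in seq_len(config$replicates)) {
    set.seed(derive_seed(config$seed, "competition", cond$medium, cond$pH,
                         rep_i))
    traj <- matrix(NA_real_, nrow = config$cycles + 1L, ncol = n,
                   dimnames = list(paste0("cycle", 0:config$cycles), ids))
    f <- rep(1 / n, n)
    traj[1L, ] <- f
    for (cyc in seq_len(config$cycles)) {
      f <- if (cond$mating_permissive) {
        mating_cycle_update(f, m)
      } else {
        vegetative_passage_update(f, w, config$generations)
      }
      if (!is.null(config$drift_cells)) {
        f <- as.vector(stats::rmultinom(1L, config$drift_cells, f)) /
          config$drift_cells
      }
      traj[cyc + 1L, ] <- f
    }
    trajectories[[rep_i]] <- traj
  }
  structure(list(trajectories = trajectories, condition = cond,
                 config = config),
            class = "competition_run")
}

#' Simulate amplicon reads for one sequenced sample
#'
#' Draws genotype counts multinomially with probabilities equal to the
#' population frequencies, then builds one read per draw:
#' random left pad + `AAGAAT` anchor motif + 24-nt genotype barcode +
#' random right pad, padded to `read_length`. The motif offset is uniform
#' in `[0, read_length - 30]`; pads are regenerated if they would introduce
#' an additional motif occurrence (or one upstream of the intended anchor).
#' Per-base substitution errors are applied at `config$error_rate`; the
#' quality string is constant.
#'
#' @param freqs Named (or library-ordered) frequency vector summing to 1.
#' @param library A `variant_library`.
#' @param config A [sim_config()].
#' @param sample_name Sample label used in read names.
#' @param seed Seed for this sample's draws (default: derived from
#'   `config$seed` and `sample_name`).
#' @return An `amplicon_reads` object: list with `sequences` (character
#'   vector of length `reads_per_sample`), `genotype` (source variant id per
#'   read), `counts` (the multinomial draw, named by variant), and
#'   `sample_name`.
#' @export
simulate_reads <- function(freqs, library, config, sample_name = "sample",
                           seed = derive_seed(config$seed, "reads",
                                              sample_name)) {
  stopifnot(inherits(library, "variant_library"),
            inherits(config, "sim_config"))
  ids <- library$variants$variant_id
  stopifnot(length(freqs) == length(ids))
  .assert_frequencies(freqs)
  n <- config$reads_per_sample

  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1L, n, freqs))
  g <- sample(rep.int(seq_along(ids), counts))
  reads <- .cpp_assemble_reads(g, library$variants$barcode, BARCODE_MOTIF,
                               config$read_length, config$error_rate)

  structure(list(sequences = reads,
                 genotype = ids[g],
                 counts = stats::setNames(counts, ids),
                 sample_name = sample_name,
                 read_length = config$read_length),
            class = "amplicon_reads")
}

#' Write simulated reads as FASTQ
#'
#' Four-line FASTQ records with a constant quality string; gzip compression
#' is selected by a `.gz` path suffix.
#'
#' @param reads An `amplicon_reads` object (or plain character vector of
#'   sequences).
#' @param path Output FASTQ path (`.fastq` or `.fastq.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- if (inherits(reads, "amplicon_reads")) reads$sequences else reads
  name <- if (inherits(reads, "amplicon_reads")) reads$sample_name else "read"
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0(name, ":", seq_along(seqs))
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate a full multi-condition sequencing experiment
#'
#' Runs [run_competition()] per condition, then emits one sequenced sample
#' per replicate at cycle 0 (the equal-frequency starting pool) and at the
#' final cycle, as the pooled screen sequences its first and last time
#' points. Samples are named `<medium>_pH<pH>_c<cycle>_r<replicate>`.
#'
#' @param library A `variant_library`.
#' @param profiles Named list of `fitness_profile`s.
#' @param conditions List of [condition()]s.
#' @param config A [sim_config()].
#' @param outdir Directory for FASTQ files and the sample manifest TSV;
#'   `NULL` keeps reads in memory (faster; used by the end-to-end checks).
#' @param sample_cycles Cycles at which samples are sequenced. The default
#'   sequences the starting pool and the final cycle; contrast-only
#'   experiments may sequence just the final cycle.
#' @return List with `manifest` (data.frame: `sample, fastq_path, medium,
#'   pH, temperature_C, cycle, replicate, seed`), `reads` (named list of
#'   `amplicon_reads`, present when `outdir` is `NULL`), and `truth` (the
#'   `competition_run` per condition).
#' @export
simulate_experiment <- function(library, profiles, conditions, config,
                                outdir = NULL,
                                sample_cycles = c(0L, config$cycles)) {
  stopifnot(all(sample_cycles %in% 0:config$cycles))
  if (inherits(conditions, "assay_condition")) conditions <- list(conditions)
  runs <- list()
  manifest <- list()
  reads <- list()
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  for (cond in conditions) {
    cond_label <- sprintf("%s_pH%s", cond$medium, format(cond$pH))
    run <- run_competition(library, profiles, cond, config)
    runs[[cond_label]] <- run
    for (rep_i in seq_len(config$replicates)) {
      traj <- run$trajectories[[rep_i]]
      for (cyc in as.integer(sample_cycles)) {
        sample_name <- sprintf("%s_c%d_r%d", cond_label, cyc, rep_i)
        seed_i <- derive_seed(config$seed, "reads", sample_name)
        rs <- simulate_reads(traj[cyc + 1L, ], library, config,
                             sample_name = sample_name, seed = seed_i)
        path <- NA_character_
        if (is.null(outdir)) {
          reads[[sample_name]] <- rs
        } else {
          path <- file.path(outdir, paste0(sample_name, ".fastq"))
          write_fastq(rs, path)
        }
        manifest[[length(manifest) + 1L]] <- data.frame(
          sample = sample_name, fastq_path = path, medium = cond$medium,
          pH = cond$pH, temperature_C = cond$temperature_C, cycle = cyc,
          replicate = rep_i, seed = seed_i, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  list(manifest = manifest,
       reads = if (is.null(outdir)) reads else NULL,
       truth = runs)
}

#' Simulate and demultiplex an experiment sample-by-sample
#'
#' Streaming counterpart of [simulate_experiment()] + `count_experiment()`:
#' each sample's reads are generated, demultiplexed with
#' [count_sample()] and discarded before the next sample, so memory stays
#' flat regardless of sequencing depth. Counts are identical to writing
#' FASTQ and re-counting (the demultiplexer consumes the same sequences).
#'
#' @inheritParams simulate_experiment
#' @param chunk_reads Samples deeper than this many reads are generated and
#'   demultiplexed in multinomial chunks (infinitely-divisible draws, so
#'   the pooled counts are one multinomial draw of the full depth).
#' @return List with `count_table` (a `count_table` over all samples) and
#'   `truth` (the `competition_run` per condition).
#' @export
simulate_and_count <- function(library, profiles, conditions, config,
                               sample_cycles = c(0L, config$cycles),
                               chunk_reads = 2e6) {
  if (inherits(conditions, "assay_condition")) conditions <- list(conditions)
  stopifnot(all(sample_cycles %in% 0:config$cycles))
  ids <- library$variants$variant_id
  runs <- list()
  manifest <- list()
  counts <- list()
  unmatched <- integer()
  totals <- integer()
  for (cond in conditions) {
    cond_label <- sprintf("%s_pH%s", cond$medium, format(cond$pH))
    run <- run_competition(library, profiles, cond, config)
    runs[[cond_label]] <- run
    for (rep_i in seq_len(config$replicates)) {
      traj <- run$trajectories[[rep_i]]
      for (cyc in as.integer(sample_cycles)) {
        sample_name <- sprintf("%s_c%d_r%d", cond_label, cyc, rep_i)
        seed_i <- derive_seed(config$seed, "reads", sample_name)
        n_left <- config$reads_per_sample
        block <- 0L
        acc <- NULL
        while (n_left > 0L) {
          block <- block + 1L
          n_block <- min(n_left, as.integer(chunk_reads))
          cfg_block <- config
          cfg_block$reads_per_sample <- n_block
          rs <- simulate_reads(traj[cyc + 1L, ], library, cfg_block,
                               sample_name = sample_name,
                               seed = derive_seed(seed_i, "chunk", block))
          cs <- count_sample(rs, library)
          if (is.null(acc)) {
            acc <- cs
          } else {
            acc$counts <- acc$counts + cs$counts
            acc$unmatched <- acc$unmatched + cs$unmatched
            acc$total_reads <- acc$total_reads + cs$total_reads
          }
          n_left <- n_left - n_block
        }
        counts[[sample_name]] <- acc$counts
        unmatched[sample_name] <- acc$unmatched
        totals[sample_name] <- acc$total_reads
        manifest[[length(manifest) + 1L]] <- data.frame(
          sample = sample_name, fastq_path = NA_character_,
          medium = cond$medium, pH = cond$pH,
          temperature_C = cond$temperature_C, cycle = cyc,
          replicate = rep_i, seed = seed_i, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  count_mat <- do.call(cbind, counts)
  rownames(count_mat) <- ids
  ct <- structure(list(counts = count_mat, samples = manifest,
                       unmatched = unmatched, total_reads = totals),
                  class = "count_table")
  list(count_table = ct, truth = runs)
}

#' Write / read a sample manifest TSV
#'
#' @param manifest Manifest data.frame as produced by
#'   [simulate_experiment()].
#' @param path TSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
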