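#' Extract the genotype barcode from amplicon reads
#'
#' Locates the first occurrence of the `AAGAAT` anchor motif in each read
#' and returns the 24 bases immediately downstream. Reads lacking the
#' motif, or with fewer than 24 bases after it, yield `NA`.
#'
#' @param read_sequence Character vector of A/C/G/T/N read sequences.
#' @return Character vector of 24-mers, `NA` where no barcode can be
#'   extracted.
#' @export
extract_barcode <- function(read_sequence) {
  read_sequence <- toupper(read_sequence)
  first <- stringi::stri_locate_first_fixed(read_sequence,
                                            BARCODE_MOTIF)[, 2L]
  bc <- stringi::stri_sub(read_sequence, first + 1L, first + BARCODE_LENGTH)
  bc[is.na(first) | stringi::stri_length(bc) < BARCODE_LENGTH |
       is.na(bc)] <- NA_character_
  bc
}

#' Demultiplex one sample's reads into genotype counts
#'
#' Applies [extract_barcode()] to every read and assigns it by exact match
#' against the library's barcode index (no mismatch tolerance by default:
#' library barcodes can differ by a single nucleotide, so fuzzy matching
#' risks misassignment). Reads without motif, with a truncated barcode, or
#' with an unknown barcode are tallied as `unmatched`.
#'
#' @param fastq Either the path of a FASTQ file (plain or gzip), an
#'   `amplicon_reads` object, or a character vector of read sequences.
#' @param library A `variant_library`.
#' @param hamming1_rescue If `TRUE`, reads whose barcode is an exact match
#'   to no library barcode but within Hamming distance 1 of exactly one are
#'   additionally counted in a separate `rescued` tally (never merged into
#'   the exact counts).
#' @return List with `counts` (named integer vector over library variants),
#'   `unmatched` (integer), `total_reads` (integer), and `rescued` (named
#'   integer vector, only when `hamming1_rescue = TRUE`).
#' @export
count_sample <- function(fastq, library, hamming1_rescue = FALSE) {
  stopifnot(inherits(library, "variant_library"),
            length(library$barcode_index) > 0L)
  seqs <- if (inherits(fastq, "amplicon_reads")) {
    fastq$sequences
  } else if (is.character(fastq) && length(fastq) == 1L &&
             file.exists(fastq)) {
    read_fastq_sequences(fastq)
  } else if (is.character(fastq)) {
    fastq
  } else {
    stop("fastq must be a file path, an amplicon_reads object, ",
         "or a character vector of sequences")
  }
  ids <- library$variants$variant_id
  total <- length(seqs)
  assigned <- if (total > 0L) {
    .cpp_assign_reads(seqs, library$variants$barcode, BARCODE_MOTIF)
  } else {
    integer(0)
  }
  counts <- stats::setNames(tabulate(assigned, nbins = length(ids)), ids)
  out <- list(counts = counts,
              unmatched = total - sum(counts),
              total_reads = total)
  if (hamming1_rescue && total > 0L) {
    rescued <- stats::setNames(integer(length(ids)), ids)
    bc <- extract_barcode(seqs[assigned == 0L])
    miss <- bc[!is.na(bc)]
    if (length(miss) > 0L) {
      lib_bc <- names(library$barcode_index)
      bc_chars <- vapply(lib_bc, utf8ToInt, integer(BARCODE_LENGTH))
      hd <- vapply(miss, function(b) {
        dv <- colSums(bc_chars != utf8ToInt(b))
        if (sum(dv == 1L) == 1L) lib_bc[which(dv == 1L)] else NA_character_
      }, character(1))
      tab <- table(factor(library$barcode_index[hd[!is.na(hd)]],
                          levels = ids))
      rescued[names(tab)] <- as.integer(tab)
    }
    out$rescued <- rescued
  }
  out
}

# Read sequences from a FASTQ file via Biostrings; on a malformed file,
# rescan to report the index of the offending record.
read_fastq_sequences <- function(path) {
  tryCatch(
    as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
    error = function(e) {
      idx <- .locate_bad_fastq_record(path)
      stop("malformed FASTQ record at index ", idx, " in '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
}

.locate_bad_fastq_record <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n_rec <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L) return(n_rec + 1L)
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad) > 0L) bad[1L] else n_rec
}

#' Assemble a genotype x sample count table from a sequencing experiment
#'
#' Demultiplexes every sample listed in a manifest (or every in-memory read
#' set) and collects the counts into a `count_table`.
#'
#' @param samples Either a manifest data.frame with columns `sample` and
#'   `fastq_path` (plus metadata columns, carried through), or a named list
#'   of `amplicon_reads` objects with an accompanying `manifest`.
#' @param library A `variant_library`.
#' @param manifest Optional manifest data.frame when `samples` is a list of
#'   read sets.
#' @return A `count_table`: list with `counts` (genotype x sample integer
#'   matrix), `samples` (metadata data.frame), `unmatched` and
#'   `total_reads` (named integer vectors).
#' @export
count_experiment <- function(samples, library, manifest = NULL) {
  if (is.data.frame(samples)) {
    manifest <- samples
    readers <- lapply(manifest$fastq_path, identity)
    names(readers) <- manifest$sample
  } else {
    stopifnot(is.list(samples), !is.null(manifest))
    readers <- samples[manifest$sample]
  }
  per_sample <- lapply(readers, count_sample, library = library)
  counts <- vapply(per_sample, `[[`, integer(nrow(library$variants)),
                   "counts")
  rownames(counts) <- library$variants$variant_id
  structure(
    list(counts = counts,
         samples = manifest,
         unmatched = vapply(per_sample, `[[`, integer(1), "unmatched"),
         total_reads = vapply(per_sample, `[[`, integer(1), "total_reads")),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "genotypes x", ncol(x$counts),
      "samples\n")
  cat("matched reads per sample:",
      paste(utils::head(colSums(x$counts), 6L), collapse = ", "),
      if (ncol(x$counts) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Flag samples below the sequencing-depth floor
#'
#' The pooled screen requires a minimum number of matched reads per sample
#' (4x10^5 by default). Samples below the floor are flagged `warn`; no data
#' are dropped.
#'
#' @param count_table A `count_table`.
#' @param min_reads Depth floor on matched reads.
#' @return Data.frame with columns `sample`, `matched_reads`, `flag`
#'   (`"pass"` / `"warn"`).
#' @export
check_depth <- function(count_table, min_reads = 400000) {
  matched <- colSums(count_table$counts)
  data.frame(sample = colnames(count_table$counts),
             matched_reads = as.integer(matched),
             flag = ifelse(matched >= min_reads, "pass", "warn"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a count table as TSV
#'
#' Genotypes as rows and samples as columns, with two extra rows
#' `unmatched` and `total_reads`; integers are written exactly.
#'
#' @param count_table A `count_table`.
#' @param path TSV path.
#' @export
write_counts <- function(count_table, path) {
  mat <- rbind(count_table$counts,
               unmatched = count_table$unmatched,
               total_reads = count_table$total_reads)
  df <- data.frame(genotype = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param samples Optional sample metadata data.frame to re-attach.
#' @export
read_counts <- function(path, samples = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$genotype
  extra <- c("unmatched", "total_reads")
  stopifnot(all(extra %in% rownames(mat)))
  counts <- mat[setdiff(rownames(mat), extra), , drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 samples = samples,
                 unmatched = as.integer(mat["unmatched", ]),
                 total_reads = as.integer(mat["total_reads", ])),
            class = "count_table")
}
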