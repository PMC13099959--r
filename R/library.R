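#' One-codon-per-amino-acid table used to build variant barcodes
#'
#' Returns the codon table used to translate an 8-residue variable region
#' into a 24-nt DNA barcode (one codon per amino acid, so barcodes are a
#' bijection onto peptide sequences). The default table ships with the
#' package and uses a high-usage *S. pombe* codon for each amino acid.
#'
#' @param path Optional path to a two-column TSV (`aa`, `codon`) overriding
#'   the shipped table.
#' @return Named character vector mapping one-letter amino-acid codes to
#'   3-nt codons.
#' @examples
#' pombe_codons()[["Y"]]
#' @export
pombe_codons <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "spombe_codons.tsv", package = "matefit")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "codon") %in% names(tab)))
  codons <- stats::setNames(toupper(tab$codon), toupper(tab$aa))
  .validate_codon_map(codons)
  codons
}

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.validate_codon_map <- function(codon_map) {
  aas <- names(codon_map)
  if (!all(AMINO_ACIDS %in% aas)) {
    stop("codon_map must cover all 20 amino acids; missing: ",
         paste(setdiff(AMINO_ACIDS, aas), collapse = ", "))
  }
  if (anyDuplicated(codon_map[AMINO_ACIDS])) {
    stop("codon_map must be injective: duplicated codons would make ",
         "barcodes collide")
  }
  if (!all(nchar(codon_map) == 3L) ||
      !all(grepl("^[ACGT]{3}$", codon_map))) {
    stop("codons must be 3-nt strings over {A,C,G,T}")
  }
  invisible(codon_map)
}

#' Enumerate the single-substitution peptide variant library
#'
#' Builds the panel of all single amino-acid substitution variants of a
#' nine-residue mature pheromone peptide, plus the wild type, and assigns
#' each genotype a unique 24-nt DNA barcode (the concatenated codons of
#' residues 1-8). Position 9 is the farnesylated cysteine and is excluded
#' from mutagenesis, so the full panel over positions 1-8 holds
#' 8 x 19 = 152 substitution variants and 153 genotypes in total.
#'
#' Variants are named `<WTaa><position><SUBaa>` on the 1-based
#' mature-peptide coordinate (e.g. `P6H`; the corresponding precursor
#' allele name adds an offset of +30, `mfm1-P36H`). Order is deterministic:
#' wild type first, then by position, then substitution alphabetically.
#'
#' @param wt_peptide 9-character mature peptide, ending in `C`.
#'   Default is the *S. pombe* M-factor sequence.
#' @param variable_positions Integer residue indices to mutate; must be a
#'   subset of 1..8.
#' @param codon_map Injective amino-acid-to-codon mapping, as returned by
#'   [pombe_codons()].
#' @return A `variant_library` object: list with `variants` (data.frame with
#'   columns `variant_id`, `position`, `wt_residue`, `sub_residue`,
#'   `peptide`, `barcode`), `barcode_index` (named character vector mapping
#'   24-mers to variant ids) and `wt_peptide`.
#' @examples
#' lib <- enumerate_library()
#' nrow(lib$variants)  # 153
#' @export
enumerate_library <- function(wt_peptide = "YTPKVPYMC",
                              variable_positions = 1:8,
                              codon_map = pombe_codons()) {
  wt_peptide <- toupper(wt_peptide)
  if (nchar(wt_peptide) != 9L) {
    stop("wt_peptide must have length exactly 9")
  }
  if (substr(wt_peptide, 9L, 9L) != "C") {
    stop("wt_peptide must end in the farnesylated cysteine 'C'")
  }
  wt_res <- strsplit(wt_peptide, "")[[1]]
  if (!all(wt_res %in% AMINO_ACIDS)) {
    stop("wt_peptide contains non-standard residues")
  }
  variable_positions <- sort(unique(as.integer(variable_positions)))
  if (length(variable_positions) == 0L ||
      !all(variable_positions %in% 1:8)) {
    stop("variable_positions must be a non-empty subset of 1..8 ",
         "(position 9 is the invariant cysteine)")
  }
  .validate_codon_map(codon_map)

  barcode_of <- function(peptide_chars) {
    paste(codon_map[peptide_chars[1:8]], collapse = "")
  }

  rows <- list(data.frame(
    variant_id = "WT",
    position = NA_integer_,
    wt_residue = NA_character_,
    sub_residue = NA_character_,
    peptide = wt_peptide,
    barcode = barcode_of(wt_res),
    stringsAsFactors = FALSE
  ))
  for (pos in variable_positions) {
    subs <- setdiff(AMINO_ACIDS, wt_res[pos])
    for (aa in sort(subs)) {
      pep <- wt_res
      pep[pos] <- aa
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = paste0(wt_res[pos], pos, aa),
        position = pos,
        wt_residue = wt_res[pos],
        sub_residue = aa,
        peptide = paste(pep, collapse = ""),
        barcode = barcode_of(pep),
        stringsAsFactors = FALSE
      )
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  stopifnot(!anyDuplicated(variants$variant_id),
            !anyDuplicated(variants$barcode),
            all(nchar(variants$barcode) == BARCODE_LENGTH))

  structure(
    list(
      variants = variants,
      barcode_index = stats::setNames(variants$variant_id, variants$barcode),
      wt_peptide = wt_peptide
    ),
    class = "variant_library"
  )
}

#' @export
print.variant_library <- function(x, ...) {
  cat("variant_library:", nrow(x$variants), "genotypes",
      sprintf("(wild type %s + %d substitutions)\n",
              x$wt_peptide, nrow(x$variants) - 1L))
  cat("barcodes:", BARCODE_LENGTH, "nt, unique\n")
  invisible(x)
}

#' Look up a 24-mer barcode in a variant library
#'
#' Exact-match lookup of a barcode against the library's barcode index.
#'
#' @param library A `variant_library`.
#' @param kmer Character vector of 24-character DNA strings.
#' @return Character vector of variant ids, `NA` where the barcode is not
#'   in the library. `NA` inputs (e.g. reads without an extractable
#'   barcode) propagate as `NA`.
#' @export
lookup_barcode <- function(library, kmer) {
  stopifnot(inherits(library, "variant_library"))
  if (any(nchar(kmer[!is.na(kmer)]) != BARCODE_LENGTH)) {
    stop("kmer must have length exactly ", BARCODE_LENGTH)
  }
  unname(library$barcode_index[kmer])
}

#' Write / read a variant library as TSV
#'
#' The on-disk format is a UTF-8, tab-separated table with a header line and
#' columns `variant_id, position, wt_residue, sub_residue, peptide, barcode`.
#'
#' @param library A `variant_library`.
#' @param path Output (or input) file path.
#' @return `write_library()` returns `path` invisibly; `read_library()`
#'   returns a `variant_library`.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "variant_library"))
  utils::write.table(library$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  # explicit classes: single-letter residue columns (e.g. all "T") must
  # not be parsed as logicals
  variants <- utils::read.delim(
    path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
    colClasses = c(variant_id = "character", position = "integer",
                   wt_residue = "character", sub_residue = "character",
                   peptide = "character", barcode = "character"))
  required <- c("variant_id", "position", "wt_residue", "sub_residue",
                "peptide", "barcode")
  if (!all(required %in% names(variants))) {
    stop("library TSV must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id) || anyDuplicated(variants$barcode)) {
    stop("variant_id and barcode must be unique within a library")
  }
  wt <- variants$peptide[variants$variant_id == "WT"]
  if (length(wt) != 1L) stop("library TSV must contain exactly one WT row")
  structure(
    list(
      variants = variants,
      barcode_index = stats::setNames(variants$variant_id, variants$barcode),
      wt_peptide = wt
    ),
    class = "variant_library"
  )
}
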