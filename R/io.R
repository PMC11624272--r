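#' Read and write pipeline files
#'
#' Plain-text readers/writers for every table the pipeline exchanges:
#' FASTA genomes, BED-style peak/blacklist files (0-based half-open, no
#' header), and headered TSVs for bins, pixels, loop calls, gene
#' annotation, contrasts, expression and survival. All writers are inverses
#' of the matching readers.
#'
#' @param path File path.
#' @param genome Named character vector of sequences.
#' @name stagloop-io
NULL

#' @rdname stagloop-io
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname stagloop-io
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname stagloop-io
#' @param peaks Peak tibble; columns beyond `chrom`, `start`, `end` are
#'   written as BED extra fields in order.
#' @export
write_peaks_bed <- function(peaks, path) {
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  readr::write_tsv(peaks |> relocate("chrom", "start", "end"), path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname stagloop-io
#' @param extra_cols Names for BED fields after `chrom`, `start`, `end`.
#' @export
read_peaks_bed <- function(path, extra_cols = character(0)) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", extra_cols),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname stagloop-io
#' @param x A tibble to write.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname stagloop-io
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname stagloop-io
#' @param m A `contact_matrix`.
#' @param prefix Output prefix; writes `<prefix>.bins.tsv` and
#'   `<prefix>.pixels.tsv`.
#' @export
write_contact_matrix <- function(m, prefix) {
  readr::write_tsv(m$bins, paste0(prefix, ".bins.tsv"))
  readr::write_tsv(m$pixels, paste0(prefix, ".pixels.tsv"))
  invisible(prefix)
}

#' @rdname stagloop-io
#' @param bins_path,pixels_path Paths to a bin table and pixel table TSV.
#' @param condition,normalized Metadata for the rebuilt matrix.
#' @export
read_contact_matrix <- function(bins_path, pixels_path,
                                condition = NA_character_,
                                normalized = "raw") {
  bins <- read_table_tsv(bins_path)
  pixels <- read_table_tsv(pixels_path)
  contact_matrix(bins, pixels, condition = condition, normalized = normalized)
}
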