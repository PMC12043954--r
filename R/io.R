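# Readers/writers for the pipeline's plain-text interchange formats.

#' Read viral unit sequences from FASTA
#'
#' Headers follow the `unitID|scaffoldN|sampleID` convention used by
#' [write_community()]; records sharing a `unitID` are treated as scaffolds
#' of one unit and are N-linked in the returned table.
#'
#' @param path FASTA file.
#' @param spacer_length N-spacer used when a unit has several scaffolds.
#' @return Tibble `unit_id`, `sample_id`, `n_scaffolds`, `length` (non-N),
#'   `sequence`.
#' @export
read_units_fasta <- function(path, spacer_length = 1500L) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 3)
  tibble(unit_id = parts[, 1],
         sample_id = parts[, 3],
         sequence = as.character(seqs)) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(sample_id = .data$sample_id[1],
                     n_scaffolds = dplyr::n(),
                     length = sum(nchar(.data$sequence)),
                     sequence = link_scaffolds(.data$sequence, spacer_length),
                     .groups = "drop")
}

#' Read protein sequences from FASTA
#'
#' Headers follow `proteinID|unitID|sampleID`.
#'
#' @param path FASTA file.
#' @return Tibble `protein_id`, `unit_id`, `sample_id`, `sequence`.
#' @export
read_proteins_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 3)
  tibble(protein_id = parts[, 1], unit_id = parts[, 2],
         sample_id = parts[, 3], sequence = as.character(seqs))
}

#' Read a tab-separated table
#'
#' Thin wrapper over [readr::read_tsv()] with quiet column typing, for the
#' pipeline's TSV interchange tables (samples, bins, abundance, annotation
#' hits, host assignments).
#'
#' @param path TSV file with a header row.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a tab-separated table
#'
#' @param x Data frame.
#' @param path Output file.
#' @return `x`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' Write curated units as N-linked FASTA
#'
#' @param units Unit table from [build_units()].
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_units_fasta <- function(units, path) {
  seqs <- Biostrings::DNAStringSet(units$sequence)
  names(seqs) <- sprintf("%s|scaffold1|%s", units$unit_id, units$sample_id)
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}
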