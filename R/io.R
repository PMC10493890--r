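# File-format adapters: FASTA for sequences, TSV for result tables.

#' Read and write sequences as FASTA
#'
#' Thin adapters over Biostrings FASTA I/O returning plain named character
#' vectors.
#'
#' @param x Named character vector of sequences.
#' @param path FASTA file path.
#' @return Writers return `path` invisibly; readers a named character
#'   vector.
#' @export
write_protein_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x), path)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
read_protein_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), names(s))
}

#' @rdname write_protein_fasta
#' @export
write_dna_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
read_dna_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

# TSV with "# key: value" provenance header lines.
#' @noRd
write_tsv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, as.character, "")), con)
  }
  write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an enrichment table as TSV
#'
#' @param table An `enrichment_table` ([variant_enrichment()]).
#' @param path Output path.
#' @param provenance Optional named list written as `# key: value` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(table, path, provenance = NULL) {
  write_tsv_provenance(table, path, provenance)
}

#' Write a position enrichment matrix as TSV
#'
#' Rows are diversified positions, columns amino acids.
#'
#' @param mat A `position_enrichment` matrix.
#' @param path Output path.
#' @param provenance Optional named list of header metadata.
#' @return `path`, invisibly.
#' @export
write_position_matrix_tsv <- function(mat, path, provenance = NULL) {
  df <- data.frame(position = rownames(mat), unclass(mat),
                   check.names = FALSE)
  write_tsv_provenance(df, path, provenance)
}

#' Write campaign sorting statistics as TSV
#'
#' One row per sorting round, mirroring a sorting-statistics table: round,
#' inducer concentration, events scanned, cells collected, percent
#' collected.
#'
#' @param stats The `stats` tibble from [run_campaign()].
#' @param path Output path.
#' @param provenance Optional named list of header metadata.
#' @return `path`, invisibly.
#' @export
write_campaign_stats_tsv <- function(stats, path, provenance = NULL) {
  write_tsv_provenance(stats, path, provenance)
}
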