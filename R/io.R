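#' Write extraction records to TSV
#'
#' @param records Extraction records data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_insert_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write valid peptides to FASTA
#'
#' @param records Extraction records data.frame; valid rows are written.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_valid_fasta <- function(records, path) {
  keep <- records$validity == "valid"
  aa <- Biostrings::AAStringSet(records$peptide[keep])
  names(aa) <- records$read_id[keep]
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write the per-class extraction summary as JSON
#'
#' @param summary Named integer vector of class counts (from
#'   [extract_all()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_class_summary <- function(summary, path) {
  jsonlite::write_json(as.list(summary), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a peptide list (FASTA or one-per-line text)
#'
#' Isolate peptide sets for overlap comparison come either as FASTA or
#' as a plain text file with one peptide per line.
#'
#' @param path Input path.
#' @return Character vector of peptides.
#' @export
read_peptide_list <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) > 0 && startsWith(first, ">")) {
    as.character(Biostrings::readAAStringSet(path))
  } else {
    lines <- trimws(readLines(path))
    lines[nzchar(lines)]
  }
}
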