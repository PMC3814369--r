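#' Read subunit sequences from FASTA
#'
#' Reads a FASTA file into an `AAStringSet`, uppercasing sequences and
#' validating that only the 20 standard one-letter amino-acid codes
#' occur. Record order is preserved. The file is read through
#' `Biostrings::readBStringSet` so that non-standard characters are
#' detected rather than silently dropped.
#'
#' @param file path to a FASTA file.
#' @return an [Biostrings::AAStringSet] named by the FASTA headers (first
#'   whitespace-delimited token).
#' @export
readSubunitFasta <- function(file) {
  raw <- Biostrings::readBStringSet(file)
  if (length(raw) == 0L)
    stop("no FASTA records found in ", file)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm))
    stop("duplicate sequence name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[i], "")[[1]], .AA_CODES)
    if (length(bad))
      stop(sprintf("record '%s' contains non-amino-acid character(s): %s",
                   nm[i], paste(unique(bad), collapse = "")))
    if (!nzchar(seqs[i]))
      stop(sprintf("record '%s' has an empty sequence", nm[i]))
  }
  Biostrings::AAStringSet(stats::setNames(seqs, nm))
}

#' Write subunit sequences to FASTA
#'
#' @param sequences `AAStringSet` or named character vector.
#' @param file output path.
#' @export
writeSubunitFasta <- function(sequences, file) {
  seqs <- asSequenceVector(sequences)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), filepath = file)
  invisible(file)
}
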