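# FASTA I/O, delegated to Biostrings.

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  set <- Biostrings::readBStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("writing FASTA requires the Biostrings package")
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
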