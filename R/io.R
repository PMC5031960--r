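# Thin FASTA wrappers around Biostrings, so simulator output and screen
# input share one format path.

#' Read and write protein FASTA
#'
#' @param path file path.
#' @return `read_fasta()`: a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path)
  invisible(path)
}
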