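#' Read sequences or an alignment from FASTA
#'
#' Reads an amino-acid FASTA file (aligned or not) into a named character
#' vector. For an alignment all sequences must share one length.
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, error unless all sequences have equal length.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) abort(paste0("FASTA not found: ", path))
  ss <- Biostrings::readAAStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  if (aligned && length(unique(nchar(seqs))) > 1) {
    abort("alignment FASTA has sequences of unequal length")
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
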