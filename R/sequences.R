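#' Read DNA sequences from a FASTA file
#'
#' Loads a (multi-record) FASTA file and returns the sequences as a named
#' character vector of uppercase DNA strings over the alphabet \{A,C,G,T,N\}.
#' Lowercase (soft-masked) residues are uppercased on load; any other
#' character is rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_dna <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  validate_dna(seqs)
  seqs
}

validate_dna <- function(seqs) {
  if (length(seqs) == 0L || any(!nzchar(seqs)))
    stop("empty DNA sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence '", names(seqs)[bad][1L] %||% which(bad)[1L],
         "' contains characters outside {A,C,G,T,N}")
  invisible(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings (may contain N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dna <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
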