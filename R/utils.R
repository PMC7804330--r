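# Shared sequence helpers. The internal alphabet is DNA: U is converted to T
# on input and back to U only when RNA FASTA output is requested.

canonical_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

is_acgt <- function(x) {
  !grepl("[^ACGT]", x)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (ACGT).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_percent <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  100 * gc / n
}

# split a sequence into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
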