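#' Read genome sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file into a named character vector of
#' uppercase-normalized DNA sequences. Only the characters A, C, G, T and N
#' are accepted; anything else (after uppercasing, with U converted to T)
#' raises an error naming the offending symbol.
#'
#' @param path Path to a FASTA file.
#' @param source_tag Optional strain/species label attached as an attribute
#'   to every sequence.
#' @return Named character vector of DNA sequences.
#' @export
read_genome_fasta <- function(path, source_tag = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) validate_dna(seqs[[i]], names(seqs)[i])
  if (!is.null(source_tag)) attr(seqs, "source_tag") <- source_tag
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(set))) names(set) <- paste0("seq", seq_along(set))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate a DNA string
#'
#' Uppercases the input and checks it against the {A,C,G,T,N} alphabet.
#'
#' @param x A single character string.
#' @param id Label used in error messages.
#' @return The uppercased string, invisibly usable.
#' @export
validate_dna <- function(x, id = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  bad <- unique(strsplit(gsub("[ACGTN]", "", x), "")[[1]])
  if (length(bad) > 0) {
    stop(sprintf("sequence '%s' contains non-DNA character(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Reverse complement of a DNA string
#'
#' @param x A single DNA string (A/C/G/T/N, case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# substring helper on 1-based closed coordinates, with bounds check
subseq_chk <- function(x, start, end, what = "span") {
  n <- nchar(x)
  if (start < 1 || end > n || start > end) {
    stop(sprintf("%s [%d,%d] outside sequence of length %d", what, start, end, n),
         call. = FALSE)
  }
  substr(x, start, end)
}
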