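#' Read a FASTA file of nucleotide sequences
#'
#' Thin wrapper around \code{\link[Biostrings]{readDNAStringSet}} that
#' normalizes residues (uppercase, U mapped to T, as found in assorted
#' GenBank dumps) and validates that every character is an IUPAC
#' nucleotide code.
#'
#' @param path path to a FASTA file (wrapped or unwrapped records).
#' @return a \link[Biostrings]{DNAStringSet}, one element per record, in
#'   file order; names are the first whitespace-delimited token of each
#'   header.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgu"), tf)
#' as.character(readFasta(tf))
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !any(startsWith(lines, ">")))
    stop("no records in FASTA file: ", path)
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    if (hdr[k] + 1L > ends[k]) return("")
    paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[ \t]", "", seqs))
  seqs <- chartr("U", "T", seqs)
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k])) stop("empty sequence for record '", ids[k], "'")
    bad <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")),
                   seqs[k])
    if (bad > 0)
      stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                   substr(seqs[k], bad, bad), ids[k], bad))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a \link[Biostrings]{DNAStringSet} or named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' IUPAC-aware reverse complement
#'
#' @param x a character string, character vector or
#'   \link[Biostrings]{DNAStringSet}.
#' @return the reverse complement, same type as the input (character in,
#'   character out).
#' @examples
#' revComp("GAATTC")  # palindrome
#' revComp("ACGTN")
#' @export
revComp <- function(x) {
  if (is.character(x)) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else {
    Biostrings::reverseComplement(x)
  }
}
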