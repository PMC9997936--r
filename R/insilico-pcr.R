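# bitmask encoding of IUPAC codes; two codes are compatible when their
# base sets intersect
IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                V = 7L, N = 15L)

seqMask <- function(x) {
  m <- IUPAC_MASK[strsplit(toupper(x), "")[[1]]]
  if (anyNA(m)) stop("non-IUPAC character in sequence")
  unname(m)
}

# ungapped scan of one primer orientation against the + strand; returns
# match counts per offset
scanCounts <- function(tmask, pmask) {
  k <- length(pmask); L <- length(tmask)
  if (k > L) return(integer(0))
  n <- L - k + 1L
  counts <- integer(n)
  for (j in seq_len(k)) {
    counts <- counts + as.integer(bitwAnd(tmask[j:(j + n - 1L)], pmask[j]) > 0L)
  }
  counts
}

#' Scan a template for primer binding sites
#'
#' Ungapped, mismatch-tolerant search of a primer against both strands of
#' a template. The primer itself is scanned along the + strand and its
#' reverse complement is scanned along the + strand with hits reported as
#' minus-strand sites. IUPAC ambiguity codes in the primer match any
#' compatible template base. Mismatch positions are reported in primer
#' coordinates (1 = primer 5' end) and a flag marks mismatches within the
#' last 3 bases of the primer 3' end, where extension is most sensitive.
#'
#' @param template template sequence (string or DNAString(Set)).
#' @param primer primer sequence (string).
#' @param min_identity minimum percent identity of a reported site
#'   (default 60).
#' @param template_id,primer_id identifiers for the report.
#' @return data.frame with columns template_id, primer_id, strand, start,
#'   end, identity, n_mismatch, mismatch_positions (comma-separated,
#'   primer coordinates), three_prime_mismatch; sorted by identity then
#'   position. Zero rows is a valid result.
#' @examples
#' scanPrimer("CCCCGAATTCAAAA", "GAATTC")
#' @export
scanPrimer <- function(template, primer, min_identity = 60,
                       template_id = "template", primer_id = "primer") {
  template <- asSeqChar(template); primer <- asSeqChar(primer)
  if (nchar(primer) > nchar(template))
    stop("primer longer than template")
  tmask <- seqMask(template)
  k <- nchar(primer)
  res <- list()
  for (strand in c("+", "-")) {
    pseq <- if (strand == "+") primer else revComp(primer)
    pmask <- seqMask(pseq)
    counts <- scanCounts(tmask, pmask)
    hit <- which(100 * counts / k >= min_identity)
    for (o in hit) {
      cols <- bitwAnd(tmask[o:(o + k - 1L)], pmask) > 0L
      mmt <- which(!cols)  # template-orientation offsets within the site
      mm <- if (strand == "+") mmt else (k + 1L - mmt)  # primer coords
      mm <- sort(mm)
      res[[length(res) + 1L]] <- data.frame(
        template_id = template_id, primer_id = primer_id, strand = strand,
        start = o, end = o + k - 1L, identity = 100 * sum(cols) / k,
        n_mismatch = length(mm),
        mismatch_positions = paste(mm, collapse = ","),
        three_prime_mismatch = any(mm > k - 3L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(template_id = character(), primer_id = character(),
                      strand = character(), start = integer(),
                      end = integer(), identity = numeric(),
                      n_mismatch = integer(),
                      mismatch_positions = character(),
                      three_prime_mismatch = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(-out$identity, out$start), , drop = FALSE]
}

#' Predict PCR amplicons for a primer pair
#'
#' Combines forward-primer sites on the + strand with reverse-primer sites
#' on the - strand into amplicon predictions. Amplicon length includes
#' both primer footprints (reverse-site end minus forward-site start plus
#' one).
#'
#' @param template template sequence.
#' @param forward,reverse primer sequences.
#' @param min_identity minimum per-primer site identity (default 60).
#' @param max_len maximum amplicon length in bp (default 2000).
#' @param pair_label label carried into the report.
#' @param template_id template identifier.
#' @return data.frame with columns pair_label, template_id, fwd_start,
#'   fwd_identity, rev_end, rev_identity, length, sequence; sorted by
#'   combined identity. Zero rows is a valid result.
#' @export
predictAmplicons <- function(template, forward, reverse, min_identity = 60,
                             max_len = 2000, pair_label = "pair",
                             template_id = "template") {
  template <- asSeqChar(template)
  fsites <- scanPrimer(template, forward, min_identity, template_id)
  fsites <- fsites[fsites$strand == "+", , drop = FALSE]
  rsites <- scanPrimer(template, reverse, min_identity, template_id)
  rsites <- rsites[rsites$strand == "-", , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(fsites))) for (j in seq_len(nrow(rsites))) {
    len <- rsites$end[j] - fsites$start[i] + 1L
    if (len <= 0 || len > max_len) next
    res[[length(res) + 1L]] <- data.frame(
      pair_label = pair_label, template_id = template_id,
      fwd_start = fsites$start[i], fwd_identity = fsites$identity[i],
      rev_end = rsites$end[j], rev_identity = rsites$identity[j],
      length = len,
      sequence = substr(template, fsites$start[i], rsites$end[j]),
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(pair_label = character(), template_id = character(),
                      fwd_start = integer(), fwd_identity = numeric(),
                      rev_end = integer(), rev_identity = numeric(),
                      length = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(-(out$fwd_identity + out$rev_identity), out$fwd_start), ,
      drop = FALSE]
}

#' Primer-by-reference specificity matrix
#'
#' Best binding-site identity (either strand) of each primer against each
#' reference sequence, the in-silico analogue of a primer
#' specificity/efficiency screen. Cells below \code{min_identity} are NA
#' ("no site").
#'
#' @param primers data.frame with columns name, sequence (e.g.
#'   \code{loadPrimerTable()$primers}).
#' @param refs a \linkS4class{ReferenceLibrary} or named
#'   \code{DNAStringSet}.
#' @param min_identity reporting threshold (default 60).
#' @return numeric matrix, primers x references.
#' @export
specificityMatrix <- function(primers, refs, min_identity = 60) {
  seqs <- if (methods::is(refs, "ReferenceLibrary")) refSeqs(refs) else refs
  stopifnot(!is.null(names(seqs)))
  out <- matrix(NA_real_, nrow = nrow(primers), ncol = length(seqs),
                dimnames = list(primers$name, names(seqs)))
  for (i in seq_len(nrow(primers))) for (j in seq_along(seqs)) {
    sites <- scanPrimer(seqs[[j]], primers$sequence[i], min_identity,
                        template_id = names(seqs)[j],
                        primer_id = primers$name[i])
    if (nrow(sites)) out[i, j] <- sites$identity[1]
  }
  out
}

#' Forward/reverse pair specificity in "fwd%/rev%" notation
#'
#' @param forward,reverse primer sequences.
#' @param template template sequence.
#' @param min_identity reporting threshold.
#' @return character like "100/80", or NA components when no site.
#' @export
pairSpecificity <- function(forward, reverse, template, min_identity = 60) {
  f <- scanPrimer(template, forward, min_identity)
  r <- scanPrimer(template, reverse, min_identity)
  fb <- if (nrow(f)) f$identity[1] else NA_real_
  rb <- if (nrow(r)) r$identity[1] else NA_real_
  sprintf("%s/%s", ifelse(is.na(fb), "none", format(fb)),
          ifelse(is.na(rb), "none", format(rb)))
}
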