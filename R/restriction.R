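#' Find restriction recognition sites
#'
#' All 1-based start positions of a recognition motif on the + strand,
#' overlapping occurrences included. IUPAC codes in the motif are honoured.
#' For palindromic motifs such as the EcoRI site GAATTC the - strand adds
#' no further loci.
#'
#' @param seq template sequence.
#' @param motif recognition sequence (default \code{"GAATTC"}).
#' @return integer vector of start positions (possibly empty).
#' @examples
#' findRecognitionSites("AAGAATTCAA")        # 3
#' findRecognitionSites("AAGAATTTAA")        # none: single-base change
#' @export
findRecognitionSites <- function(seq, motif = "GAATTC") {
  seq <- asSeqChar(seq)
  if (!nzchar(motif)) stop("motif must be non-empty")
  m <- Biostrings::matchPattern(Biostrings::DNAString(toupper(motif)),
                                Biostrings::DNAString(seq), fixed = FALSE)
  as.integer(Biostrings::start(m))
}

#' Digest a linear molecule
#'
#' Cuts after position \code{site_start + cut_offset - 1} at every motif
#' occurrence (EcoRI: G^AATTC, \code{cut_offset = 1}). Fragment lengths
#' always sum to the template length; a template without sites yields a
#' single full-length fragment.
#'
#' @param seq template sequence.
#' @param motif recognition sequence.
#' @param cut_offset bases after which the duplex is cut, within the motif
#'   (0 < cut_offset < motif length).
#' @param template_id identifier for the report.
#' @return list with elements template_id, motif, cut_offset, site_starts,
#'   fragment_lengths.
#' @export
digestLinear <- function(seq, motif = "GAATTC", cut_offset = 1,
                         template_id = "template") {
  seq <- asSeqChar(seq)
  if (cut_offset <= 0 || cut_offset >= nchar(motif))
    stop("cut_offset must lie strictly inside the motif")
  sites <- findRecognitionSites(seq, motif)
  cuts <- sites + cut_offset - 1L
  cuts <- cuts[cuts >= 1L & cuts < nchar(seq)]
  bounds <- c(0L, cuts, nchar(seq))
  list(template_id = template_id, motif = toupper(motif),
       cut_offset = as.integer(cut_offset), site_starts = sites,
       fragment_lengths = diff(bounds))
}

#' EcoRI-based GC/AT genotype discrimination
#'
#' The GC-biased genotypes carry a GAATTC EcoRI site that the AT-biased
#' genotypes have lost through a single transition (GAATTT). Discrimination
#' is locus-specific: the reference site position is projected through a
#' global alignment onto the query, and only the homologous locus decides
#' the call, so an incidental GAATTC elsewhere in the query cannot flip it.
#'
#' @param query query sequence.
#' @param reference length-one \linkS4class{ReferenceLibrary} holding the
#'   Genotype #1 representative (must itself contain the motif).
#' @param params alignment parameters.
#' @param motif recognition sequence (default GAATTC).
#' @param min_identity projection threshold; queries below it are called
#'   ambiguous.
#' @return list with elements call ("cut" = GC-compatible, "uncut" =
#'   AT-compatible, "ambiguous"), reference_site (start in reference
#'   coordinates), query_locus (character at the homologous positions or
#'   NA).
#' @export
ecoriDiscriminate <- function(query, reference, params = alignParams(),
                              motif = "GAATTC", min_identity = 50) {
  stopifnot(methods::is(reference, "ReferenceLibrary"),
            length(reference) == 1)
  refseq <- as.character(refSeqs(reference)[[1]])
  sites <- findRecognitionSites(refseq, motif)
  if (!length(sites))
    stop("reference does not contain the recognition motif")
  site <- sites[1]
  k <- nchar(motif)
  query <- asSeqChar(query)
  aln <- try(globalAlign(refseq, query, params), silent = TRUE)
  if (inherits(aln, "try-error"))
    return(list(call = "ambiguous", reference_site = site,
                query_locus = NA_character_))
  if (percentIdentity(aln) < min_identity)
    return(list(call = "ambiguous", reference_site = site,
                query_locus = NA_character_))
  cc <- alnColumns(aln)
  cols <- which(!is.na(cc$apos) & cc$apos >= site & cc$apos <= site + k - 1L)
  qchars <- cc$b[cols]
  if (length(cols) < k || all(qchars == "-"))
    return(list(call = "ambiguous", reference_site = site,
                query_locus = NA_character_))
  locus <- paste(qchars, collapse = "")
  call <- if (identical(locus, toupper(motif))) "cut" else "uncut"
  list(call = call, reference_site = site, query_locus = locus)
}
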