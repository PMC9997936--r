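# loads the user-supplied GenBank reference library, if it has been
# fetched (scripts/fetch_references.R); NULL when unavailable
genbankLibrary <- function() {
  fa <- system.file("extdata", "genbank_its.fasta", package = "OphioITS")
  if (!nzchar(fa) || !file.exists(fa)) return(NULL)
  segs <- NULL
  segf <- system.file("extdata", "genbank_segments.tsv",
                      package = "OphioITS")
  if (nzchar(segf) && file.exists(segf)) {
    df <- utils::read.delim(segf, stringsAsFactors = FALSE)
    segs <- lapply(split(df, df$accession), function(d) {
      ir <- IRanges::IRanges(start = d$start, end = d$end)
      names(ir) <- d$segment
      ir
    })
  }
  suppressWarnings(loadReferenceLibrary(fa, segments = segs))
}
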