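#!/usr/bin/env Rscript
# Optional helper (requires network access): downloads the GenBank records
# named in the bundled registry into inst/extdata/genbank_its.fasta and, where
# the feature tables annotate ITS1 / 5.8S / ITS2, writes the segment
# annotations to inst/extdata/genbank_segments.tsv. The package core stays
# offline; run this once on a networked machine to enable the
# accession-based checks in tests/testthat/test-acceptance.R.
#
# Usage: Rscript scripts/fetch_references.R [--dest inst/extdata]

suppressMessages(library(optparse))
opts <- parse_args(OptionParser(option_list = list(
  make_option("--dest", type = "character", default = "inst/extdata")
)))

reg <- read.delim(file.path(opts$dest, "registry.tsv"),
                  stringsAsFactors = FALSE)
accs <- reg$accession
base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
fetch <- function(rettype) {
  url <- sprintf("%s?db=nuccore&id=%s&rettype=%s&retmode=text",
                 base, paste(accs, collapse = ","), rettype)
  con <- url(url)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

message("fetching FASTA for ", length(accs), " accessions ...")
fa <- fetch("fasta")
# normalize headers to bare accessions
hdr <- startsWith(fa, ">")
fa[hdr] <- sub("^>([A-Za-z0-9_]+)(\\.[0-9]+)?\\s.*$", ">\\1", fa[hdr])
writeLines(fa, file.path(opts$dest, "genbank_its.fasta"))

message("fetching feature tables ...")
ft <- tryCatch(fetch("ft"), error = function(e) character())
seg_rows <- list()
if (length(ft)) {
  cur <- NA_character_
  for (line in ft) {
    if (grepl("^>Feature", line)) {
      cur <- sub("^>Feature\\s+(?:\\w+\\|)?([A-Za-z0-9_]+)(\\.[0-9]+)?.*$",
                 "\\1", line)
      next
    }
    # coordinate lines followed by product/note naming the segment
    m <- regmatches(line, regexec("^[<>]?([0-9]+)\t[<>]?([0-9]+)\t", line))[[1]]
    if (length(m) == 3) {
      last_coords <- as.integer(m[2:3])
      next
    }
    lab <- tolower(line)
    seg <- if (grepl("spacer 1|its1", lab)) "its1"
           else if (grepl("5\\.8s", lab)) "r58s"
           else if (grepl("spacer 2|its2", lab)) "its2"
           else NA_character_
    if (!is.na(seg) && !is.na(cur) && exists("last_coords"))
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(accession = cur, segment = seg,
                   start = min(last_coords), end = max(last_coords))
  }
}
if (length(seg_rows)) {
  segs <- unique(do.call(rbind, seg_rows))
  write.table(segs, file.path(opts$dest, "genbank_segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote segment annotations for ",
          length(unique(segs$accession)), " accessions")
} else {
  message("no ITS segment annotations recovered; ",
          "provide genbank_segments.tsv manually if needed")
}
message("done")
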