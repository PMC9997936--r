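# shared helpers for building small synthetic inputs in code

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

writeTempFasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# small registry FASTA covering a few accessions of the bundled registry
syntheticRegistryFasta <- function(accessions, seed = 42) {
  set.seed(seed)
  seqs <- vapply(accessions, function(a) randomDna(60), character(1))
  writeTempFasta(as.vector(rbind(paste0(">", accessions), seqs)))
}
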