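# Shared fixtures: the packaged library and helpers that write modified
# FASTA files for negative-control tests.

fixtureFasta <- function() {
  system.file("extdata", "strand_library.fasta", package = "HairpinReplicator")
}

readFastaPlain <- function(path) {
  # minimal FASTA reader kept independent of the package's loader
  lines <- readLines(path)
  idx <- grep("^>", lines)
  ids <- sub("^>", "", lines[idx])
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i)
    paste(lines[(idx[i] + 1L):ends[i]], collapse = ""), character(1))
  stats::setNames(seqs, ids)
}

writeFasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    writeLines(seqs[[id]], con)
  }
  path
}

revcompPlain <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# brute-force shared-15-mer oracle, independent of the package's search
bruteSharedDomain <- function(seqs, bit) {
  sense <- seqs[paste0(bit, c("A", "B", "C", "D"))]
  anti <- seqs[paste0(bit, c("A", "B", "C", "D"), "*")]
  s1 <- sense[[1]]
  kmers <- unique(substring(s1, 1:(nchar(s1) - 14), 15:nchar(s1)))
  kmers[vapply(kmers, function(km)
    all(vapply(sense, function(x) grepl(km, x, fixed = TRUE), logical(1))) &&
    all(vapply(anti, function(x) grepl(revcompPlain(km), x, fixed = TRUE),
               logical(1))), logical(1))]
}

oneMolar <- function() ionicConditions(monovalent = 1000, divalentMg = 0)
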