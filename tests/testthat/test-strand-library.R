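# Strand library parsing, information-domain discovery, domain annotation,
# design validation and defective strand sets.

test_that("the packaged library loads with 16 strands of 82-84 nt", {
  lib <- loadStrandLibrary()
  info <- strandInfo(lib)
  expect_equal(nrow(info), 16L)
  expect_setequal(info$sense, c("sense", "antisense"))
  w <- Biostrings::width(strands(lib))
  expect_true(all(w >= 82 & w <= 84))
  expect_equal(nrow(unique(info[, c("bit", "position", "sense")])), 16L)
})

test_that("a missing strand is reported by its (bit, position, sense)", {
  seqs <- readFastaPlain(fixtureFasta())
  path <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(seqs[setdiff(names(seqs), "0D")], path)
  expect_error(loadStrandLibrary(path), "at least 16")
  # same gap padded back to 16 records with a duplicate id parses further
  # and is caught by the completeness check
  dup <- c(seqs[setdiff(names(seqs), "0D")], "0D*dup" = unname(seqs[["0D*"]]))
  names(dup)[16] <- "0C"
  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(dup, path2)
  expect_error(loadStrandLibrary(path2), "duplicate|0, D, sense")
})

test_that("non-ACGT characters are rejected with their position", {
  seqs <- readFastaPlain(fixtureFasta())
  s <- seqs[["0A"]]
  substr(s, 10, 10) <- "N"
  seqs[["0A"]] <- s
  path <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(seqs, path)
  expect_error(loadStrandLibrary(path), "0A.*position 10")
})

test_that("information-domain discovery matches the brute-force oracle", {
  seqs <- readFastaPlain(fixtureFasta())
  lib <- findInformationDomains(loadStrandLibrary())
  doms <- infoDomains(lib)
  expect_equal(unname(doms[["0"]]), "AGTGGGTAATAATGA")
  expect_equal(unname(doms[["1"]]), "AAAAGAAGAGAAAGA")
  for (bit in c("0", "1")) {
    brute <- bruteSharedDomain(seqs, bit)
    expect_length(brute, 1L)
    expect_equal(unname(doms[[bit]]), brute)
  }
})

test_that("domain discovery is involutive under strand-set complementation", {
  lib <- findInformationDomains(loadStrandLibrary())
  info <- strandInfo(lib)
  for (bit in c("0", "1")) {
    sense <- strands(lib)[info$id[info$bit == bit & info$sense == "sense"]]
    anti <- strands(lib)[info$id[info$bit == bit & info$sense == "antisense"]]
    swapped <- findSharedDomain(anti, sense)
    expect_equal(swapped, revcompPlain(unname(infoDomains(lib)[[bit]])))
  }
})

test_that("sense-only collections cannot confirm an information domain", {
  lib <- loadStrandLibrary()
  info <- strandInfo(lib)
  senseOnly <- strandLibrary(strands(lib)[info$id[info$sense == "sense"]])
  expect_error(findInformationDomains(senseOnly), "no antisense")
})

test_that("annotations tile each strand exactly with a central 15-nt domain", {
  lib <- annotateLibrary(loadStrandLibrary())
  ann <- annotations(lib)
  w <- stats::setNames(Biostrings::width(strands(lib)), names(strands(lib)))
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    expect_equal(a$h5Start, 1L)
    expect_equal(a$h3End, unname(w[a$id]))
    expect_equal(a$infoStart, a$h5End + 1L)
    expect_equal(a$h3Start, a$infoEnd + 1L)
    expect_equal(a$infoEnd - a$infoStart + 1L, 15L)
    h5len <- a$h5End - a$h5Start + 1L
    h3len <- a$h3End - a$h3Start + 1L
    expect_true(h5len >= 30 && h5len <= 37)
    expect_true(h3len >= 30 && h3len <= 37)
  }
  # antisense strands carry the reverse complement of the sense domain
  info <- strandInfo(lib)
  for (id in info$id[info$sense == "antisense"]) {
    a <- ann[ann$id == id, ]
    span <- substring(as.character(strands(lib)[[id]]), a$infoStart, a$infoEnd)
    bit <- info$bit[info$id == id]
    expect_equal(span, revcompPlain(unname(infoDomains(lib)[[bit]])))
  }
})

test_that("design validation confirms backbone complementarity and Tm ordering", {
  lib <- annotateLibrary(loadStrandLibrary())
  rep <- validateDesign(lib)
  expect_true(all(rep$pairs$stretch >= 20))
  expect_true(all(rep$pairs$pass))
  # thermodynamic ordering: info domains melt below the oscillation peak,
  # backbone duplexes above the amplification-robustness bound
  expect_true(all(rep$infoTm < 67))
  expect_true(all(rep$pairs$backboneTm > 74))
  expect_true(rep$orderingOK)
  # info-domain melting near the 48 C working point (model tolerance)
  expect_lt(abs(rep$infoTm[["1"]] - 48), 3)
  expect_lt(abs(rep$infoTm[["0"]] - 48), 3)
})

test_that("a scrambled hairpin region is flagged without disturbing other pairs", {
  seqs <- readFastaPlain(fixtureFasta())
  s <- seqs[["0A"]]
  ann <- annotations(annotateLibrary(loadStrandLibrary()))
  a <- ann[ann$id == "0A", ]
  h3len <- a$h3End - a$h3Start + 1L
  scramble <- paste(rep(c("A", "C"), length.out = h3len), collapse = "")
  seqs[["0A"]] <- paste0(substring(s, 1, a$infoEnd), scramble)
  lib2 <- annotateLibrary(strandLibrary(seqs))
  rep2 <- validateDesign(lib2)
  broken <- rep2$pairs[rep2$pairs$from == "0A", ]
  expect_false(any(broken$pass))
  expect_true(all(rep2$pairs$pass[rep2$pairs$from != "0A"]))
})

test_that("defective strand sets drop the template-matching sense strands", {
  full <- strandsForTemplate("0000", "++++")
  expect_length(full@included, 16L)
  one <- strandsForTemplate("0000", "+++-")
  expect_setequal(setdiff(full@included, one@included), "0D")
  two <- strandsForTemplate("0000", "++--")
  expect_setequal(setdiff(full@included, two@included), c("0C", "0D"))
  mixed <- strandsForTemplate("0101", "-+-+")
  expect_setequal(setdiff(full@included, mixed@included), c("0A", "0C"))
  expect_error(strandsForTemplate("0000", "++-"), "4 characters")
  expect_error(strandsForTemplate("00x0"), "0/1")
})
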