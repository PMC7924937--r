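# Parsing, annotation and design validation of the double-hairpin strand
# library, and mapping of binary meta-sequences to (possibly defective)
# strand sets.

.parseStrandId <- function(id) {
  m <- regmatches(id, regexec("^([01])([ABCD])(\\*?)$", id))[[1]]
  if (length(m) == 0)
    stop(sprintf("cannot parse strand id '%s' (expected e.g. '0A' or '0A*')",
                 id))
  list(bit = m[2], position = m[3],
       sense = if (m[4] == "*") "antisense" else "sense")
}

.strandInfoFromIds <- function(ids, dyes = NA_character_) {
  parsed <- lapply(ids, .parseStrandId)
  data.frame(
    id = ids,
    bit = vapply(parsed, `[[`, character(1), "bit"),
    position = vapply(parsed, `[[`, character(1), "position"),
    sense = vapply(parsed, `[[`, character(1), "sense"),
    dye = rep_len(dyes, length(ids)),
    stringsAsFactors = FALSE)
}

#' Construct a strand library from sequences
#'
#' Low-level constructor; most users should call [loadStrandLibrary] on a
#' FASTA file. Completeness (one strand per bit/position/sense combination)
#' is enforced by the loader, not here, so that deliberately incomplete
#' libraries (knockouts, sense-only subsets) can be represented.
#'
#' @param sequences a named [Biostrings::DNAStringSet]; names are strand ids
#'   (`0A`..`1D`, antisense with trailing `*`).
#' @param dyes optional character vector of dye labels per strand.
#' @return A [StrandLibrary-class].
#' @export
strandLibrary <- function(sequences, dyes = NA_character_) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences))) stop("sequences must be named by strand id")
  info <- .strandInfoFromIds(names(sequences), dyes)
  new("StrandLibrary", sequences = sequences, strandInfo = info,
      infoDomains = character(0),
      annotations = data.frame())
}

#' Load and validate the strand library from FASTA
#'
#' Reads the strand library, checks the alphabet and 82--84 nt lengths, and
#' verifies that all 16 (bit, position, sense) combinations are present.
#' FASTA headers carry the strand id as the first whitespace-separated
#' token (antisense marked by a trailing `*`); an optional second token of
#' the form `dye=NAME` records a covalent label.
#'
#' @param path path to the FASTA file. Defaults to the packaged library of
#'   the 16 replicator strands.
#' @return A validated [StrandLibrary-class]; information domains are not
#'   yet identified (see [findInformationDomains]).
#' @examples
#' lib <- loadStrandLibrary()
#' lib
#' @export
loadStrandLibrary <- function(path = system.file("extdata",
                                                 "strand_library.fasta",
                                                 package = "HairpinReplicator")) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 16)
    stop(sprintf("expected at least 16 strand records, found %d", length(seqs)))
  headers <- names(seqs)
  tokens <- strsplit(headers, "\\s+")
  ids <- vapply(tokens, `[`, character(1), 1L)
  dyes <- vapply(tokens, function(tk) {
    dye <- grep("^dye=", tk[-1], value = TRUE)
    if (length(dye)) sub("^dye=", "", dye[1]) else NA_character_
  }, character(1))
  names(seqs) <- ids

  bad <- grepl("[^ACGT]", as.character(seqs))
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- regexpr("[^ACGT]", as.character(seqs[[i]]))
    stop(sprintf("strand %s contains non-ACGT character at position %d",
                 ids[i], as.integer(pos)))
  }

  lib <- strandLibrary(seqs, dyes)
  .checkComplete(lib)
  lib
}

.checkComplete <- function(lib) {
  info <- lib@strandInfo
  expected <- expand.grid(bit = c("0", "1"), position = c("A", "B", "C", "D"),
                          sense = c("sense", "antisense"),
                          stringsAsFactors = FALSE)
  have <- paste(info$bit, info$position, info$sense)
  missing <- expected[!paste(expected$bit, expected$position,
                             expected$sense) %in% have, ]
  if (nrow(missing) > 0)
    stop(sprintf("missing strand(s) for (bit, position, sense): %s",
                 paste(sprintf("(%s, %s, %s)", missing$bit, missing$position,
                               missing$sense), collapse = ", ")))
  invisible(TRUE)
}

#' @describeIn strands sequences of a strand library.
#' @export
setMethod("strands", "StrandLibrary", function(x) x@sequences)

#' @describeIn strandInfo metadata of a strand library.
#' @export
setMethod("strandInfo", "StrandLibrary", function(x) x@strandInfo)

#' @describeIn infoDomains information domains of a strand library (empty
#'   until [findInformationDomains] has been run).
#' @export
setMethod("infoDomains", "StrandLibrary", function(x) x@infoDomains)

#' @describeIn annotations domain annotations (empty until
#'   [annotateLibrary] has been run).
#' @export
setMethod("annotations", "StrandLibrary", function(x) x@annotations)

#' Find a k-mer shared by all sense strands whose reverse complement is
#' shared by all antisense strands
#'
#' Workhorse behind [findInformationDomains], exposed for use on arbitrary
#' strand collections (e.g. random-pool negative controls).
#'
#' @param sense [Biostrings::DNAStringSet] of sense strands.
#' @param antisense [Biostrings::DNAStringSet] of antisense strands.
#' @param k k-mer length (default 15).
#' @return The unique shared k-mer as a character scalar.
#' @export
findSharedDomain <- function(sense, antisense, k = 15) {
  if (length(sense) == 0) stop("no sense strands supplied")
  if (length(antisense) == 0)
    stop("no antisense strands supplied: cannot confirm a shared domain by ",
         "reverse complement")
  s1 <- as.character(sense[[1]])
  if (nchar(s1) < k) stop("strands shorter than k")
  starts <- seq_len(nchar(s1) - k + 1)
  kmers <- unique(substring(s1, starts, starts + k - 1))
  inAll <- function(kmer, set) {
    all(Biostrings::vcountPattern(kmer, set) > 0)
  }
  hits <- kmers[vapply(kmers, function(km) {
    inAll(km, sense) &&
      inAll(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(km))), antisense)
  }, logical(1))]
  if (length(hits) == 0)
    stop(sprintf("no shared %d-mer found across the strand set", k))
  if (length(hits) > 1)
    stop(sprintf("ambiguous shared %d-mers: %s", k,
                 paste(hits, collapse = ", ")))
  hits
}

#' Identify the information domains of a library
#'
#' For each bit, finds the unique 15-mer present in all four sense strands
#' of that bit whose reverse complement is present in all four antisense
#' strands of the bit.
#'
#' @param lib a [StrandLibrary-class].
#' @param k domain length (default 15).
#' @return The library with its `infoDomains` slot filled (named by bit).
#' @examples
#' lib <- findInformationDomains(loadStrandLibrary())
#' infoDomains(lib)
#' @export
findInformationDomains <- function(lib, k = 15) {
  info <- lib@strandInfo
  doms <- character(0)
  for (b in sort(unique(info$bit))) {
    senseIds <- info$id[info$bit == b & info$sense == "sense"]
    antiIds <- info$id[info$bit == b & info$sense == "antisense"]
    doms[[b]] <- findSharedDomain(lib@sequences[senseIds],
                                  lib@sequences[antiIds], k = k)
  }
  lib@infoDomains <- doms
  lib
}

#' Annotate the domain architecture of one strand
#'
#' Locates the information domain by exact substring match (sense strands)
#' or reverse-complement match (antisense strands) and assigns the 5' and 3'
#' stem-loop (hairpin) regions as the flanking prefix and suffix. Spans are
#' 1-based and closed and tile the strand exactly.
#'
#' @param id strand id.
#' @param lib a [StrandLibrary-class] with information domains identified.
#' @return A one-row data.frame with columns id, h5Start, h5End, infoStart,
#'   infoEnd, h3Start, h3End.
#' @export
annotateStrand <- function(id, lib) {
  if (length(lib@infoDomains) == 0)
    stop("information domains not yet identified; run findInformationDomains")
  row <- lib@strandInfo[lib@strandInfo$id == id, ]
  if (nrow(row) != 1) stop(sprintf("unknown strand id '%s'", id))
  dom <- lib@infoDomains[[row$bit]]
  pattern <- if (row$sense == "sense") dom else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(dom)))
  subject <- lib@sequences[[id]]
  m <- Biostrings::matchPattern(pattern, subject)
  if (length(m) == 0)
    stop(sprintf("information domain not found in strand %s", id))
  if (length(m) > 1)
    stop(sprintf("information domain occurs %d times in strand %s",
                 length(m), id))
  s <- Biostrings::start(m)[1]
  e <- Biostrings::end(m)[1]
  len <- length(subject)
  if (s <= 1 || e >= len)
    stop(sprintf("information domain touches the end of strand %s", id))
  data.frame(id = id, h5Start = 1L, h5End = s - 1L,
             infoStart = s, infoEnd = e,
             h3Start = e + 1L, h3End = len, stringsAsFactors = FALSE)
}

#' Annotate all strands of a library
#'
#' @param lib a [StrandLibrary-class] with information domains identified
#'   (run through [findInformationDomains] first, or it is run here).
#' @return The library with its `annotations` slot filled.
#' @examples
#' lib <- annotateLibrary(loadStrandLibrary())
#' head(annotations(lib))
#' @export
annotateLibrary <- function(lib) {
  if (length(lib@infoDomains) == 0) lib <- findInformationDomains(lib)
  ann <- do.call(rbind, lapply(lib@strandInfo$id, annotateStrand, lib = lib))
  lib@annotations <- ann
  lib
}

# longest stretch of `a` (5'->3') complementary to a window of `b`
# (5'->3'), allowing at most maxMismatch mismatched pairs; returns the
# aligned top/bottom strings of the best stretch
.longestComplementaryStretch <- function(a, b, maxMismatch = 3) {
  rb <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(rb, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- list(len = 0L, mism = 0L, top = "", bottom = "")
  for (off in seq(-(nb - 1L), na - 1L)) {
    i0 <- max(1L, 1L + off); i1 <- min(na, nb + off)
    if (i1 - i0 + 1L <= best$len) next
    match <- av[i0:i1] == bv[(i0 - off):(i1 - off)]
    # two-pointer longest window with <= maxMismatch mismatches
    lo <- 1L; mism <- 0L
    n <- length(match)
    for (hi in seq_len(n)) {
      if (!match[hi]) mism <- mism + 1L
      while (mism > maxMismatch) {
        if (!match[lo]) mism <- mism - 1L
        lo <- lo + 1L
      }
      if (hi - lo + 1L > best$len) {
        ia <- i0 + lo - 1L; ib <- i0 + hi - 1L
        top <- paste(av[ia:ib], collapse = "")
        # bottom 3'->5' aligned: complement of the matched window of rb
        bot <- paste(.complementVec(bv[(ia - off):(ib - off)]), collapse = "")
        best <- list(len = hi - lo + 1L, mism = sum(!match[lo:hi]),
                     top = top, bottom = bot)
      }
    }
  }
  best
}

#' Validate the design rules of a strand library
#'
#' Checks, per bit and consecutive position pair (A->B->C->D->A, periodic),
#' the backbone complementarity between the 3' hairpin of each sense strand
#' and the 5' hairpin of the next sense strand (longest complementary
#' stretch allowing a bounded number of mismatches), and the thermodynamic
#' ordering Tm(information-domain duplex) < Tm(backbone duplexes).
#'
#' @param lib a [StrandLibrary-class] (annotated on the fly if needed).
#' @param conditions buffer [IonicConditions-class] for the Tm computations.
#' @param maxMismatch mismatches tolerated inside a complementary stretch
#'   (default 3; the stems carry designed mismatches).
#' @param minStretch stretch length below which a pair is flagged (default 20).
#' @return A list with `pairs` (data.frame: bit, from, to, stretch,
#'   mismatches, backboneTm, pass), `infoTm` (named numeric per bit) and
#'   `orderingOK` (all info Tm below all backbone Tm).
#' @examples
#' rep <- validateDesign(loadStrandLibrary())
#' rep$orderingOK
#' @export
validateDesign <- function(lib, conditions = ionicConditions(),
                           maxMismatch = 3, minStretch = 20) {
  if (nrow(lib@annotations) == 0) lib <- annotateLibrary(lib)
  ann <- lib@annotations
  info <- lib@strandInfo
  positions <- c("A", "B", "C", "D")
  rows <- list()
  for (b in sort(unique(info$bit))) {
    for (i in seq_along(positions)) {
      from <- paste0(b, positions[i])
      to <- paste0(b, positions[ifelse(i == 4, 1, i + 1)])
      aFrom <- ann[ann$id == from, ]
      aTo <- ann[ann$id == to, ]
      h3 <- substring(as.character(lib@sequences[[from]]),
                      aFrom$h3Start, aFrom$h3End)
      h5 <- substring(as.character(lib@sequences[[to]]),
                      aTo$h5Start, aTo$h5End)
      st <- .longestComplementaryStretch(h3, h5, maxMismatch)
      btm <- if (st$len >= 2)
        meltingTemperature(duplexThermo(st$top, st$bottom, conditions))
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        bit = b, from = from, to = to, stretch = st$len,
        mismatches = st$mism, backboneTm = btm,
        pass = st$len >= minStretch, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  infoTm <- vapply(lib@infoDomains, function(dom)
    meltingTemperature(duplexThermo(dom, conditions = conditions)),
    numeric(1))
  list(pairs = pairs, infoTm = infoTm,
       orderingOK = all(infoTm < min(pairs$backboneTm, na.rm = TRUE)) &&
                    all(pairs$pass))
}

#' Strand set for replicating a binary meta-sequence
#'
#' Returns the full 16-strand set minus the sense strands knocked out by the
#' defect pattern: position i is dropped when pattern character i is `-`,
#' where the dropped strand is the sense strand whose bit matches the
#' template code at that position.
#'
#' @param code binary meta-sequence, a 4-character string over 0/1 indexed
#'   by positions A--D (the system is periodic: D is followed by A).
#' @param defects defect pattern, 4 characters over `+`/`-`
#'   (default `"++++"`, the complete set).
#' @return A [StrandSet-class].
#' @examples
#' strandsForTemplate("0000", "+++-")   # lacks 0D only
#' @export
strandsForTemplate <- function(code, defects = "++++") {
  if (nchar(code) != 4L || grepl("[^01]", code))
    stop("code must be 4 characters over 0/1")
  if (nchar(defects) != 4L || grepl("[^+-]", defects))
    stop("defect pattern must be 4 characters over +/-")
  positions <- c("A", "B", "C", "D")
  all16 <- c(t(outer(c("0", "1"), positions, paste0)))
  all16 <- c(all16, paste0(all16, "*"))
  codeBits <- strsplit(code, "")[[1]]
  defv <- strsplit(defects, "")[[1]]
  drop <- paste0(codeBits, positions)[defv == "-"]
  new("StrandSet", included = setdiff(all16, drop), defectPattern = defects)
}
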