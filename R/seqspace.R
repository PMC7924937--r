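# Point-mutant sequence-space analysis of the information-domain duplex:
# exhaustive Hamming-neighborhood enumeration, free-energy distributions,
# and the binding-energy tolerance criterion.

#' Free-energy distribution over a mutant neighborhood
#'
#' Duplex free energies of one template strand against every complement at a
#' fixed Hamming distance from the perfect complement.
#'
#' @slot seq the template (top) strand, 5'->3'.
#' @slot k mutation count.
#' @slot table data.frame with one row per mutant: `mutant` (the mutated
#'   complement, 3'->5' aligned so position i pairs template position i),
#'   `positions` (comma-joined 1-based mutated indices), `terminal` (any
#'   mutated index at either end of the domain), `dG` (kcal/mol).
#' @slot conditions the [IonicConditions-class] used.
#' @slot tempC evaluation temperature for dG, degrees C.
#' @export
setClass("EnergyDistribution",
  representation(seq = "character", k = "integer", table = "data.frame",
                 conditions = "IonicConditions", tempC = "numeric"))

setMethod("show", "EnergyDistribution", function(object) {
  cat(sprintf("EnergyDistribution: %s, k = %d, %d mutants\n",
              object@seq, object@k, nrow(object@table)))
  cat(sprintf("  dG range [%.2f, %.2f] kcal/mol, mean %.2f\n",
              min(object@table$dG), max(object@table$dG),
              mean(object@table$dG)))
})

#' Enumerate complement mutants at an exact Hamming distance
#'
#' Yields every complement sequence differing from the perfect complement of
#' `seq` at exactly `k` positions, each exactly once, in deterministic
#' order: mutated position sets lexicographic, substituted bases
#' alphabetical. Mutant complements are reported 3'->5', aligned against the
#' template so position i pairs template position i.
#'
#' @param seq template strand, 5'->3'.
#' @param k exact mutation count (0 <= k <= nchar(seq)).
#' @return data.frame with columns `mutant`, `positions` (comma-joined
#'   1-based indices, empty for k = 0), `terminal`.
#' @examples
#' nrow(enumerateMutants("AGTGGGTAATAATGA", 1))   # 45 single mutants
#' @export
enumerateMutants <- function(seq, k) {
  seq <- toupper(as.character(seq))
  topv <- strsplit(seq, "")[[1]]
  n <- length(topv)
  if (any(!topv %in% .BASES)) stop("sequence contains non-ACGT characters")
  if (k < 0 || k > n) stop(sprintf("k must be in [0, %d]", n))
  perfect <- .complementVec(topv)
  if (k == 0)
    return(data.frame(mutant = paste(perfect, collapse = ""),
                      positions = "", terminal = FALSE,
                      stringsAsFactors = FALSE))
  posSets <- utils::combn(n, k)
  out <- vector("list", ncol(posSets))
  for (s in seq_len(ncol(posSets))) {
    pos <- posSets[, s]
    alts <- lapply(pos, function(p) setdiff(.BASES, perfect[p]))
    # odometer order with the last position fastest: bases alphabetical
    grid <- expand.grid(rev(alts), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, rev(seq_len(k)), drop = FALSE]
    muts <- character(nrow(grid))
    base <- perfect
    for (g in seq_len(nrow(grid))) {
      mv <- base
      mv[pos] <- as.character(grid[g, ])
      muts[g] <- paste(mv, collapse = "")
    }
    out[[s]] <- data.frame(mutant = muts,
                           positions = paste(pos, collapse = ","),
                           terminal = any(pos == 1L | pos == n),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Free energies of all k-mutant duplexes
#'
#' Computes the nearest-neighbor dG for the template against every
#' complement at Hamming distance `k`, under the given buffer. Optionally
#' caches the result as a TSV keyed by (sequence, k, conditions,
#' temperature); a later call with the same key reads the cache.
#'
#' @param seq template strand, 5'->3'.
#' @param k exact mutation count.
#' @param conditions [IonicConditions-class].
#' @param tempC free-energy evaluation temperature, degrees C (default 37).
#' @param cacheDir optional directory for the on-disk distribution cache.
#' @return An [EnergyDistribution-class].
#' @examples
#' d <- energyDistribution("AGTGGGTAATAATGA", 1)
#' fractionMeetingCriterion(d)
#' @export
energyDistribution <- function(seq, k, conditions = ionicConditions(),
                               tempC = 37, cacheDir = NULL) {
  seq <- toupper(as.character(seq))
  cacheFile <- NULL
  if (!is.null(cacheDir)) {
    cacheFile <- file.path(cacheDir, sprintf(
      "dist_%s_k%d_na%g_mg%g_ct%g_T%g.tsv", seq, k,
      conditions@monovalent, conditions@divalentMg,
      conditions@totalStrandConc, tempC))
    if (file.exists(cacheFile)) {
      tab <- utils::read.delim(cacheFile, stringsAsFactors = FALSE,
                               colClasses = c("character", "character",
                                              "logical", "numeric"))
      tab$positions[is.na(tab$positions)] <- ""
      return(new("EnergyDistribution", seq = seq, k = as.integer(k),
                 table = tab, conditions = conditions, tempC = tempC))
    }
  }
  muts <- enumerateMutants(seq, k)
  topv <- strsplit(seq, "")[[1]]
  botMat <- matrix(unlist(strsplit(muts$mutant, ""), use.names = FALSE),
                   nrow = nrow(muts), byrow = TRUE)
  e <- .stackEnergyBatch(topv, botMat)
  ds <- e$ds + .saltEntropyCorrection(length(topv), conditions)
  muts$dG <- e$dh - (tempC + 273.15) * ds / 1000
  if (!is.null(cacheFile)) {
    dir.create(dirname(cacheFile), showWarnings = FALSE, recursive = TRUE)
    utils::write.table(muts, cacheFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  new("EnergyDistribution", seq = seq, k = as.integer(k), table = muts,
      conditions = conditions, tempC = tempC)
}

#' Fraction of mutant duplexes meeting the binding-tolerance criterion
#'
#' The criterion counts duplexes whose free energy is weaker than or equal
#' to the threshold (dG >= threshold), i.e. duplexes the replication
#' mechanism can discriminate against at the peak temperature.
#'
#' @param dist an [EnergyDistribution-class].
#' @param threshold free-energy threshold, kcal/mol (default -12.5).
#' @return Fraction in \[0, 1\].
#' @export
fractionMeetingCriterion <- function(dist, threshold = -12.5) {
  mean(dist@table$dG >= threshold)
}

#' Split a mutant energy distribution by mutation position class
#'
#' Partitions the distribution into mutants whose mutated positions are all
#' internal and those touching a terminal base of the domain (first or last
#' position).
#'
#' @param dist an [EnergyDistribution-class].
#' @return A list with `internal` and `terminal` data.frames (a partition of
#'   the full table) and a `summary` data.frame of per-class count, mean and
#'   sd of dG.
#' @export
splitByPositionClass <- function(dist) {
  tab <- dist@table
  internal <- tab[!tab$terminal, , drop = FALSE]
  terminal <- tab[tab$terminal, , drop = FALSE]
  summarise <- function(df, cls) data.frame(
    class = cls, n = nrow(df),
    meanDG = if (nrow(df)) mean(df$dG) else NA_real_,
    sdDG = if (nrow(df) > 1) stats::sd(df$dG) else NA_real_,
    stringsAsFactors = FALSE)
  list(internal = internal, terminal = terminal,
       summary = rbind(summarise(internal, "internal"),
                       summarise(terminal, "terminal")))
}
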