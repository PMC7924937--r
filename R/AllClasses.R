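#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement
#'   width vcountPattern matchPattern
#' @importFrom stats optim optimize pbinom rbinom rnorm runif uniroot
#'   coef resid nls quantile sd rpois median setNames
#' @importFrom utils combn head
NULL

#' Ionic conditions of a hybridization buffer
#'
#' Holds the buffer composition used for salt correction of duplex
#' thermodynamics, and the total strand concentration (per complementary
#' pair) entering bimolecular melting temperatures. Defaults are the
#' replication buffer: 150 mM NaCl, 20 mM MgCl2, and two strands at 200 nM
#' each (400 nM total).
#'
#' @slot monovalent monovalent cation concentration, mM sodium-equivalent.
#' @slot divalentMg Mg2+ concentration, mM.
#' @slot totalStrandConc total strand concentration of the duplex pair, mol/L.
#' @export
setClass("IonicConditions",
  representation(monovalent = "numeric", divalentMg = "numeric",
                 totalStrandConc = "numeric"),
  prototype(monovalent = 150, divalentMg = 20, totalStrandConc = 4e-7),
  validity = function(object) {
    if (any(c(object@monovalent, object@divalentMg,
              object@totalStrandConc) < 0))
      return("ionic conditions must be nonnegative")
    TRUE
  })

#' Construct ionic conditions
#'
#' @param monovalent monovalent cation concentration, mM sodium-equivalent.
#' @param divalentMg Mg2+ concentration, mM.
#' @param totalStrandConc total strand concentration (both strands of the
#'   pair summed), mol/L.
#' @return An [IonicConditions-class] object.
#' @examples
#' ionicConditions()                     # replication buffer defaults
#' ionicConditions(monovalent = 1000, divalentMg = 0)   # 1 M NaCl reference
#' @export
ionicConditions <- function(monovalent = 150, divalentMg = 20,
                            totalStrandConc = 4e-7) {
  new("IonicConditions", monovalent = monovalent, divalentMg = divalentMg,
      totalStrandConc = totalStrandConc)
}

#' Two-state duplex thermodynamics
#'
#' Enthalpy and entropy of duplex formation from a nearest-neighbor sum,
#' entropy already salt-corrected to the stored ionic conditions. The free
#' energy at absolute temperature T follows as dH - T*dS/1000 (kcal/mol).
#'
#' @slot dH formation enthalpy, kcal/mol (negative for a stable duplex).
#' @slot dS formation entropy, cal/(mol K), salt-corrected.
#' @slot conditions the [IonicConditions-class] the entropy was corrected to.
#' @slot top top strand, 5'->3'.
#' @slot bottom bottom strand, 3'->5' (aligned antiparallel to `top`).
#' @slot nUnparameterized number of NN steps with no published parameters
#'   (tandem mismatches); such steps contribute no stacking.
#' @export
setClass("DuplexThermo",
  representation(dH = "numeric", dS = "numeric",
                 conditions = "IonicConditions",
                 top = "character", bottom = "character",
                 nUnparameterized = "integer"),
  validity = function(object) {
    if (length(object@dH) != 1L || length(object@dS) != 1L)
      return("dH and dS must be scalars")
    TRUE
  })

#' Two-state melting curve
#'
#' @slot temperatures temperature grid, degrees C.
#' @slot unboundFraction fraction of strands unbound at each temperature.
#' @slot tm melting temperature (unbound fraction 0.5), degrees C.
#' @slot width 10--90% transition span, degrees C.
#' @export
setClass("MeltingCurve",
  representation(temperatures = "numeric", unboundFraction = "numeric",
                 tm = "numeric", width = "numeric"),
  validity = function(object) {
    if (length(object@temperatures) != length(object@unboundFraction))
      return("temperatures and unboundFraction lengths differ")
    if (any(object@unboundFraction < -1e-9 | object@unboundFraction > 1 + 1e-9))
      return("unboundFraction outside [0, 1]")
    if (is.unsorted(object@unboundFraction[order(object@temperatures)],
                    strictly = FALSE))
      return("unboundFraction must be nondecreasing in temperature")
    TRUE
  })

#' Library of double-hairpin strands
#'
#' The set of 82--84 nt double-hairpin strands making up the replicator.
#' Strand ids combine an information bit (0/1), a position letter (A--D) and
#' the sense marker (a trailing `*` denotes the antisense partner, e.g.
#' `"0A*"`). A complete library holds one strand per (bit, position, sense)
#' combination: 16 strands.
#'
#' @slot sequences [Biostrings::DNAStringSet] of the strands, named by id.
#' @slot strandInfo data.frame with columns id, bit, position, sense, dye.
#' @slot infoDomains named character; per bit, the 15-nt sense information
#'   domain (empty until [findInformationDomains] has run).
#' @slot annotations data.frame of domain spans (1-based, closed), filled by
#'   [annotateLibrary].
#' @export
setClass("StrandLibrary",
  representation(sequences = "DNAStringSet", strandInfo = "data.frame",
                 infoDomains = "character", annotations = "data.frame"),
  validity = function(object) {
    info <- object@strandInfo
    if (anyDuplicated(info$id)) return("duplicate strand ids")
    if (!identical(names(object@sequences), info$id))
      return("sequence names and strandInfo ids disagree")
    w <- Biostrings::width(object@sequences)
    if (any(w < 82 | w > 84))
      return(sprintf("strand lengths outside 82-84 nt: %s",
                     paste(info$id[w < 82 | w > 84], collapse = ", ")))
    bad <- grepl("[^ACGT]", as.character(object@sequences))
    if (any(bad))
      return(sprintf("non-ACGT characters in strand(s): %s",
                     paste(info$id[bad], collapse = ", ")))
    TRUE
  })

#' Strand subset for a replication reaction
#'
#' A full or deliberately defective ("knockout") strand set. The defect
#' pattern is a 4-character string over `+`/`-`, one symbol per position
#' A--D; `-` marks a position whose template-matching sense strand is absent.
#'
#' @slot included ids of the strands present in the reaction.
#' @slot defectPattern the `+`/`-` pattern, e.g. `"+++-"`.
#' @export
setClass("StrandSet",
  representation(included = "character", defectPattern = "character"),
  validity = function(object) {
    if (nchar(object@defectPattern) != 4L ||
        grepl("[^+-]", object@defectPattern))
      return("defectPattern must be 4 characters over +/-")
    TRUE
  })

#' Cross-catalytic growth model
#'
#' Rates of the two-species cross-catalytic system
#' dc/dt = k*cbar + k0, dcbar/dt = k*c + k0,
#' with time in thermal-cycle units.
#'
#' @slot k cross-catalysis rate, 1/cycle.
#' @slot k0 spontaneous (untemplated) formation rate, nM/cycle.
#' @export
setClass("CrossCatalyticModel",
  representation(k = "numeric", k0 = "numeric"),
  validity = function(object) {
    if (object@k < 0 || object@k0 < 0) return("k and k0 must be nonnegative")
    TRUE
  })

#' Construct a cross-catalytic growth model
#'
#' @param k cross-catalysis rate, 1/cycle.
#' @param k0 spontaneous formation rate, nM/cycle.
#' @return A [CrossCatalyticModel-class] object.
#' @examples
#' crossCatalyticModel(k = 0.16, k0 = 0.4)
#' @export
crossCatalyticModel <- function(k, k0) new("CrossCatalyticModel", k = k, k0 = k0)

#' Serial-transfer protocol specification
#'
#' @slot cyclesPerTransfer thermal cycles between successive dilutions.
#' @slot dilution multiplicative factor applied to product species at each
#'   transfer, in (0, 1].
#' @slot nTransfers number of transfers.
#' @slot monomerReplenished if `FALSE`, fresh monomers are not supplied and
#'   growth is disabled after the start (the fading control).
#' @export
setClass("SerialTransferSpec",
  representation(cyclesPerTransfer = "numeric", dilution = "numeric",
                 nTransfers = "numeric", monomerReplenished = "logical"),
  validity = function(object) {
    if (object@dilution <= 0 || object@dilution > 1)
      return("dilution must be in (0, 1]")
    if (object@cyclesPerTransfer < 1 || object@nTransfers < 0)
      return("cyclesPerTransfer must be >= 1 and nTransfers >= 0")
    TRUE
  })

#' Construct a serial-transfer specification
#'
#' @param cyclesPerTransfer cycles between dilutions (default 3).
#' @param dilution dilution factor in (0, 1] (nominal 0.5 for 1:1 dilution).
#' @param nTransfers number of transfers.
#' @param monomerReplenished supply fresh monomers at each transfer?
#' @return A [SerialTransferSpec-class] object.
#' @examples
#' serialTransferSpec(dilution = 0.43, nTransfers = 10)
#' @export
serialTransferSpec <- function(cyclesPerTransfer = 3, dilution = 0.5,
                               nTransfers = 10, monomerReplenished = TRUE) {
  new("SerialTransferSpec", cyclesPerTransfer = cyclesPerTransfer,
      dilution = dilution, nTransfers = nTransfers,
      monomerReplenished = monomerReplenished)
}

#' Thermal-oscillation cycle protocol
#'
#' The asymmetric temperature protocol driving replication: a long hold at
#' the base temperature where templated assembly proceeds, a one-second
#' spike to the peak temperature that separates replicate from template,
#' and short ramps.
#'
#' @slot tBase base temperature, degrees C (default 45).
#' @slot tPeak peak temperature, degrees C (default 67).
#' @slot holdBase base hold, minutes (default 20).
#' @slot holdPeak peak hold, seconds (default 1).
#' @slot ramp ramp time per cycle, seconds (default 20).
#' @slot nCycles number of thermal cycles.
#' @export
setClass("CycleProtocol",
  representation(tBase = "numeric", tPeak = "numeric", holdBase = "numeric",
                 holdPeak = "numeric", ramp = "numeric", nCycles = "numeric"),
  validity = function(object) {
    if (object@tPeak <= object@tBase) return("tPeak must exceed tBase")
    if (any(c(object@holdBase, object@holdPeak, object@ramp) <= 0))
      return("durations must be positive")
    TRUE
  })

#' Construct a cycle protocol
#'
#' @param tBase base temperature, degrees C.
#' @param tPeak peak temperature, degrees C.
#' @param holdBase base hold, minutes.
#' @param holdPeak peak hold, seconds.
#' @param ramp ramp time, seconds.
#' @param nCycles number of cycles.
#' @return A [CycleProtocol-class] object.
#' @examples
#' cycleProtocol(nCycles = 6)
#' @export
cycleProtocol <- function(tBase = 45, tPeak = 67, holdBase = 20, holdPeak = 1,
                          ramp = 20, nCycles = 6) {
  new("CycleProtocol", tBase = tBase, tPeak = tPeak, holdBase = holdBase,
      holdPeak = holdPeak, ramp = ramp, nCycles = nCycles)
}

#' Binomial replication-fidelity model
#'
#' Per-information-domain fidelity as the cumulative binomial probability of
#' fewer than K per-nucleotide copying errors over an N-nt domain, given a
#' per-nucleotide fidelity p.
#'
#' @slot N information-domain length, nt.
#' @slot K tolerated mutation count (the domain still counts as faithfully
#'   replicated with up to K-1 errors).
#' @slot p per-nucleotide replication fidelity in \[0, 1\].
#' @export
setClass("FidelityModel",
  representation(N = "numeric", K = "numeric", p = "numeric"),
  validity = function(object) {
    if (object@K < 1 || object@K > object@N) return("need 1 <= K <= N")
    if (object@p < 0 || object@p > 1) return("p must be in [0, 1]")
    TRUE
  })

#' Construct a fidelity model
#'
#' @param N information-domain length, nt (default 15).
#' @param K tolerated mutation count (default 3).
#' @param p per-nucleotide fidelity.
#' @return A [FidelityModel-class] object.
#' @examples
#' fidelityModel(p = 0.85)
#' @export
fidelityModel <- function(N = 15, K = 3, p = 1) new("FidelityModel", N = N, K = K, p = p)

## ---- show methods -------------------------------------------------------

setMethod("show", "DuplexThermo", function(object) {
  cat(sprintf("DuplexThermo: %d bp duplex\n", nchar(object@top)))
  cat(sprintf("  dH = %.1f kcal/mol, dS = %.1f cal/(mol K)\n",
              object@dH, object@dS))
  cat(sprintf("  dG(37 C) = %.2f kcal/mol, Tm = %.1f C\n",
              deltaG(object), meltingTemperature(object)))
  if (object@nUnparameterized > 0L)
    cat(sprintf("  (%d unparameterized NN step(s) contributed no stacking)\n",
                object@nUnparameterized))
})

setMethod("show", "StrandLibrary", function(object) {
  cat(sprintf("StrandLibrary: %d strands (%d sense, %d antisense)\n",
              nrow(object@strandInfo),
              sum(object@strandInfo$sense == "sense"),
              sum(object@strandInfo$sense == "antisense")))
  if (length(object@infoDomains))
    for (b in names(object@infoDomains))
      cat(sprintf("  information domain %s: %s\n", b, object@infoDomains[[b]]))
  else cat("  information domains not yet identified\n")
})

setMethod("show", "CrossCatalyticModel", function(object) {
  cat(sprintf("CrossCatalyticModel: k = %.4g /cycle, k0 = %.4g nM/cycle\n",
              object@k, object@k0))
})

setMethod("show", "CycleProtocol", function(object) {
  cat(sprintf(
    "CycleProtocol: %g cycles, %g C (%g min) <-> %g C (%g s), ramp %g s\n",
    object@nCycles, object@tBase, object@holdBase, object@tPeak,
    object@holdPeak, object@ramp))
})

setMethod("show", "StrandSet", function(object) {
  cat(sprintf("StrandSet: %d strands, defect pattern %s\n",
              length(object@included), object@defectPattern))
})
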