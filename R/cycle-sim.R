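# Mechanistic per-cycle simulator of the four-step replication mechanism:
# (0) activation by fast cooling, (1) templated binding of hairpins at the
# information domains, (2) backbone closure through hairpin open-close
# fluctuations, (3) separation of replicate from template at the peak
# temperature. All probabilities derive from the thermo module's two-state
# melting behavior; in its ideal limit the simulator reduces exactly to the
# cross-catalytic growth model.

#' Mechanistic rates of the replication cycle
#'
#' Bundles the thermodynamic ingredients of the per-cycle simulator:
#' the information-domain duplex (binding occupancy at the base
#' temperature, release at the peak), the backbone duplexes (complex
#' destruction at the peak), and a two-state hairpin stability governing
#' the open-close fluctuations behind backbone closure and spontaneous
#' (untemplated) formation. The per-junction closure probability is
#' calibrated once so that the ideal-limit per-cycle gain at the reference
#' base temperature reproduces `kRef`; the spontaneous channel is
#' calibrated to `k0Ref` the same way.
#'
#' @slot infoThermo [DuplexThermo-class] of the information-domain duplex.
#' @slot backboneThermos list of [DuplexThermo-class], one per consecutive
#'   backbone duplex of the periodic assembly.
#' @slot hairpinDH hairpin stem closing enthalpy, kcal/mol.
#' @slot hairpinTm hairpin melting midpoint, degrees C (unimolecular).
#' @slot kRef reference cross-catalysis rate at `refTBase`, 1/cycle.
#' @slot k0Ref reference spontaneous formation rate at `refTBase`, nM/cycle.
#' @slot pZipBase per-junction backbone-closure probability during the base
#'   hold at `refTBase`.
#' @slot mismatchOccupancy occupancy of a mismatched (wrong-bit) strand
#'   relative to a matching strand, used when the matching strand is absent.
#' @slot nBindAttempts effective number of independent binding attempts per
#'   position during the base hold; a position stays empty (giving a 3:4
#'   partial) only with probability (1 - occupancy)^nBindAttempts.
#' @slot refTBase reference base temperature, degrees C.
#' @slot ideal logical; the ideal limit (full occupancy, certain zipping and
#'   release, no destruction, no depletion).
#' @export
setClass("MechanisticRates",
  representation(infoThermo = "DuplexThermo", backboneThermos = "list",
                 hairpinDH = "numeric", hairpinTm = "numeric",
                 kRef = "numeric", k0Ref = "numeric", pZipBase = "numeric",
                 mismatchOccupancy = "numeric", nBindAttempts = "numeric",
                 refTBase = "numeric", ideal = "logical"))

#' Build mechanistic rates from a strand library
#'
#' Derives the information-domain duplex (bit 0) and the four backbone
#' duplexes from the library, and sets the calibration constants.
#'
#' @param lib a [StrandLibrary-class] (annotated on the fly if needed).
#' @param conditions buffer [IonicConditions-class].
#' @param hairpinDH hairpin closing enthalpy, kcal/mol (default -60).
#' @param hairpinTm hairpin melting midpoint, degrees C (default 52).
#' @param kRef calibrated cross-catalysis rate, 1/cycle (default 0.16).
#' @param k0Ref calibrated spontaneous rate, nM/cycle (default 0.4).
#' @param pZipBase per-junction closure probability at the reference base
#'   temperature (default 0.9).
#' @param mismatchOccupancy relative occupancy of a wrong-bit strand when
#'   the matching strand is absent (default 0.1).
#' @param nBindAttempts effective binding attempts per position during the
#'   base hold (default 4).
#' @param refTBase reference base temperature, degrees C (default 45).
#' @param ideal construct the ideal limit (default FALSE).
#' @return A [MechanisticRates-class].
#' @examples
#' rates <- mechanisticRates(loadStrandLibrary())
#' @export
mechanisticRates <- function(lib, conditions = ionicConditions(),
                             hairpinDH = -60, hairpinTm = 52,
                             kRef = 0.16, k0Ref = 0.4, pZipBase = 0.9,
                             mismatchOccupancy = 0.1, nBindAttempts = 4,
                             refTBase = 45, ideal = FALSE) {
  if (nrow(lib@annotations) == 0) lib <- annotateLibrary(lib)
  rep0 <- validateDesign(lib, conditions)
  pairs0 <- rep0$pairs[rep0$pairs$bit == "0", ]
  ann <- lib@annotations
  bb <- lapply(seq_len(nrow(pairs0)), function(i) {
    from <- pairs0$from[i]; to <- pairs0$to[i]
    aF <- ann[ann$id == from, ]; aT <- ann[ann$id == to, ]
    st <- .longestComplementaryStretch(
      substring(as.character(lib@sequences[[from]]), aF$h3Start, aF$h3End),
      substring(as.character(lib@sequences[[to]]), aT$h5Start, aT$h5End))
    duplexThermo(st$top, st$bottom, conditions)
  })
  new("MechanisticRates",
      infoThermo = duplexThermo(lib@infoDomains[["0"]],
                                conditions = conditions),
      backboneThermos = bb, hairpinDH = hairpinDH, hairpinTm = hairpinTm,
      kRef = kRef, k0Ref = k0Ref, pZipBase = pZipBase,
      mismatchOccupancy = mismatchOccupancy, nBindAttempts = nBindAttempts,
      refTBase = refTBase, ideal = ideal)
}

# hairpin open fraction from a unimolecular two-state stem
.fOpen <- function(rates, tempC) {
  dS <- 1000 * rates@hairpinDH / (rates@hairpinTm + 273.15)
  tK <- tempC + 273.15
  dG <- rates@hairpinDH - tK * dS / 1000  # closing free energy
  1 / (1 + exp(-dG * 1000 / (.GAS_CONSTANT * tK)))
}

# information-domain occupancy of a matching strand on the template
.occupancy <- function(rates, tempC) {
  if (rates@ideal) return(1)
  1 - unboundFraction(rates@infoThermo, tempC)
}

# per-junction backbone closure probability during the base hold
.pZip <- function(rates, tempC) {
  if (rates@ideal) return(1)
  z <- -log(1 - rates@pZipBase) / .fOpen(rates, rates@refTBase)
  1 - exp(-z * .fOpen(rates, tempC))
}

# probability that a position is filled during the base hold
# (repeated binding attempts against the single-attempt occupancy)
.fillProb <- function(rates, occ) {
  if (rates@ideal) return(rep(1, length(occ)))
  1 - (1 - occ)^rates@nBindAttempts
}

# calibrated per-cycle templated gain prefactor (before occupancies);
# the templated rate is binding-limited, so the single-attempt occupancy
# gates the gain, while .fillProb only decides full vs partial product
.templatedPrefactor <- function(rates, tempC) {
  if (rates@ideal) return(rates@kRef)
  ref <- .occupancy(rates, rates@refTBase)^4 * .pZip(rates, rates@refTBase)^4
  rates@kRef * .pZip(rates, tempC)^4 / ref
}

# spontaneous (untemplated) formation rate, nM/cycle
.spontRate <- function(rates, tempC) {
  if (rates@ideal) return(rates@k0Ref)
  rates@k0Ref * (.fOpen(rates, tempC) / .fOpen(rates, rates@refTBase))^2
}

# probability that a new replicate separates from its template at the peak
.pRelease <- function(rates, tempC) {
  if (rates@ideal) return(1)
  unboundFraction(rates@infoThermo, tempC)
}

# probability that a complex is destroyed (any backbone duplex melts)
.pDestroy <- function(rates, tempC) {
  if (rates@ideal) return(0)
  1 - prod(vapply(rates@backboneThermos,
                  function(d) 1 - unboundFraction(d, tempC), numeric(1)))
}

#' Species pool of a replication reaction
#'
#' Deterministic concentrations (nM) of the species tracked per cycle:
#' free monomers per strand id, active templates of either sense (free
#' tetramers able to template), inactive product (replicates not yet
#' released from their templates), and the partial (3:4-type) pool.
#'
#' @slot code the 4-bit meta-sequence being replicated.
#' @slot monomers named numeric, free monomer concentration per strand id.
#' @slot senseActive,antiActive active template concentrations, nM.
#' @slot senseInactive,antiInactive unreleased product, nM.
#' @slot partials partial (one-gap) assemblies, nM (trimer equivalents).
#' @export
setClass("SpeciesPool",
  representation(code = "character", monomers = "numeric",
                 senseActive = "numeric", antiActive = "numeric",
                 senseInactive = "numeric", antiInactive = "numeric",
                 partials = "numeric"),
  validity = function(object) {
    if (any(c(object@monomers, object@senseActive, object@antiActive,
              object@senseInactive, object@antiInactive,
              object@partials) < -1e-9))
      return("concentrations must be nonnegative")
    TRUE
  })

#' Construct a species pool
#'
#' @param code 4-bit meta-sequence, e.g. `"0000"`.
#' @param strandSet a [StrandSet-class] (defaults to the full 16-strand
#'   set for `code`).
#' @param monomerConc monomer concentration per included strand, nM.
#' @param senseTemplate,antiTemplate initial active template
#'   concentrations, nM (templates are prepared separately and not debited
#'   from the monomer pool).
#' @return A [SpeciesPool-class].
#' @examples
#' speciesPool("0000", antiTemplate = 30)
#' @export
speciesPool <- function(code = "0000", strandSet = strandsForTemplate(code),
                        monomerConc = 200, senseTemplate = 0,
                        antiTemplate = 0) {
  monomers <- stats::setNames(rep(monomerConc, length(strandSet@included)),
                              strandSet@included)
  new("SpeciesPool", code = code, monomers = monomers,
      senseActive = senseTemplate, antiActive = antiTemplate,
      senseInactive = 0, antiInactive = 0, partials = 0)
}

# total strand material, nM of strands (for mass-conservation checks)
.poolMaterial <- function(pool) {
  sum(pool@monomers) +
    4 * (pool@senseActive + pool@antiActive +
         pool@senseInactive + pool@antiInactive) +
    3 * pool@partials
}

# exact propagation of the affine linear system
#   dcs/dt = ks*ca + k0s,  dca/dt = ka*cs + k0a
# over time dt (matrix-exponential solution, with degenerate branches)
.propagateGrowth <- function(cs, ca, ks, ka, k0s, k0a, dt = 1) {
  kap <- sqrt(ks * ka)
  if (kap > 1e-12) {
    ch <- cosh(kap * dt); sh <- sinh(kap * dt)
    csT <- ch * cs + (ks / kap) * sh * ca + (sh / kap) * k0s +
      (ch - 1) * k0a / ka
    caT <- (ka / kap) * sh * cs + ch * ca + (ch - 1) * k0s / ks +
      (sh / kap) * k0a
  } else if (ks > 1e-12) {
    caT <- ca + k0a * dt
    csT <- cs + ks * (ca * dt + k0a * dt^2 / 2) + k0s * dt
  } else if (ka > 1e-12) {
    csT <- cs + k0s * dt
    caT <- ca + ka * (cs * dt + k0s * dt^2 / 2) + k0a * dt
  } else {
    csT <- cs + k0s * dt
    caT <- ca + k0a * dt
  }
  c(csT, caT)
}

# monomer availability factor (saturating in free monomer concentration)
.availability <- function(m, kHalf = 5) m / (m + kHalf)

# strand ids used to assemble a replicate of the given sense, position by
# position; a position with no usable strand yields NA (gap)
.strandUsage <- function(pool, sense = c("sense", "antisense")) {
  sense <- match.arg(sense)
  bits <- strsplit(pool@code, "")[[1]]
  positions <- c("A", "B", "C", "D")
  suffix <- if (sense == "sense") "" else "*"
  vapply(seq_len(4), function(i) {
    want <- paste0(bits[i], positions[i], suffix)
    if (want %in% names(pool@monomers)) return(want)
    alt <- paste0(ifelse(bits[i] == "0", "1", "0"), positions[i], suffix)
    if (alt %in% names(pool@monomers)) return(alt)
    NA_character_
  }, character(1))
}

# per-position occupancy for assembling a replicate of the given sense
.positionOccupancy <- function(pool, rates, tempC, usage, sense) {
  occ <- .occupancy(rates, tempC)
  bits <- strsplit(pool@code, "")[[1]]
  positions <- c("A", "B", "C", "D")
  suffix <- if (sense == "sense") "" else "*"
  vapply(seq_len(4), function(i) {
    id <- usage[i]
    if (is.na(id)) return(0)
    o <- occ
    if (id != paste0(bits[i], positions[i], suffix))
      o <- o * rates@mismatchOccupancy   # wrong-bit incorporation
    if (!rates@ideal)
      o <- o * .availability(pool@monomers[[id]])
    o
  }, numeric(1))
}

#' Advance the species pool by one thermal cycle
#'
#' Applies the four mechanistic steps in order: activation (all free
#' hairpins closed), templated binding with the information-domain
#' occupancy at the base temperature (wrong-bit incorporation at reduced
#' occupancy when the matching strand is absent), backbone closure with the
#' per-junction zip probability (all four junctions give product, a single
#' gap gives the partial 3:4 pool) plus the spontaneous channel, then
#' separation at the peak temperature: new product is released as template
#' with the info-duplex unbound fraction and all complexes are destroyed
#' with the backbone unbound fraction, crediting monomers back. Growth
#' within the base hold is integrated exactly, so the ideal limit
#' reproduces the cross-catalytic closed form.
#'
#' @param pool a [SpeciesPool-class].
#' @param protocol a [CycleProtocol-class].
#' @param rates a [MechanisticRates-class].
#' @param stochastic draw molecule-count outcomes instead of expectations.
#' @param scale molecules per nM for the stochastic variant (default 100).
#' @return The advanced [SpeciesPool-class].
#' @export
stepCycle <- function(pool, protocol, rates, stochastic = FALSE,
                      scale = 100) {
  tB <- protocol@tBase; tP <- protocol@tPeak
  useS <- .strandUsage(pool, "sense")
  useA <- .strandUsage(pool, "antisense")
  occS <- .positionOccupancy(pool, rates, tB, useS, "sense")
  occA <- .positionOccupancy(pool, rates, tB, useA, "antisense")
  fillS <- .fillProb(rates, occS)
  fillA <- .fillProb(rates, occA)
  zip <- .pZip(rates, tB)
  prefJ <- .templatedPrefactor(rates, tB) / max(zip^4, 1e-300)

  kS <- prefJ * zip^4 * prod(occS)  # sense replicates on antisense templates
  kA <- prefJ * zip^4 * prod(occA)
  avail1 <- function(usage) prod(vapply(usage[!is.na(usage)], function(id)
    if (rates@ideal) 1 else .availability(pool@monomers[[id]]), numeric(1)))
  k0S <- .spontRate(rates, tB) * avail1(useS) * all(!is.na(useS))
  k0A <- .spontRate(rates, tB) * avail1(useA) * all(!is.na(useA))

  grown <- .propagateGrowth(pool@senseActive, pool@antiActive,
                            kS, kA, k0S, k0A)
  dS <- max(grown[1] - pool@senseActive, 0)
  dA <- max(grown[2] - pool@antiActive, 0)

  # one-gap (3:4) channel: one position stays empty over the whole hold
  # while the other three fill; two internal junctions close instead of four
  oneGap <- function(fill) sum(vapply(seq_len(4), function(i)
    (1 - fill[i]) * prod(fill[-i]), numeric(1)))
  dPart <- prefJ * zip^2 *
    (oneGap(fillS) * pool@antiActive + oneGap(fillA) * pool@senseActive)

  if (stochastic) {
    draw <- function(x) stats::rpois(1, max(x, 0) * scale) / scale
    dS <- draw(dS); dA <- draw(dA); dPart <- draw(dPart)
  }

  # monomer debit: new assemblies consume their strands (templates were
  # prepared separately and are never debited)
  if (!rates@ideal) {
    applyDebit <- function(mon, dS, dA, dPart) {
      for (i in seq_len(4)) {
        if (!is.na(useS[i])) mon[useS[i]] <- mon[useS[i]] - dS
        if (!is.na(useA[i])) mon[useA[i]] <- mon[useA[i]] - dA
      }
      partIds <- head(useS[!is.na(useS)], 3)
      for (id in partIds) mon[id] <- mon[id] - dPart
      mon
    }
    debit <- applyDebit(pool@monomers, dS, dA, dPart)
    if (any(debit < 0)) {
      short <- debit < 0
      f <- min(pool@monomers[short] / (pool@monomers[short] - debit[short]))
      dS <- dS * f; dA <- dA * f; dPart <- dPart * f
      debit <- applyDebit(pool@monomers, dS, dA, dPart)
    }
    pool@monomers <- pmax(debit, 0)
  }

  # separation at the peak: release new and previously retained product
  pRel <- .pRelease(rates, tP)
  relS <- dS + pool@senseInactive
  relA <- dA + pool@antiInactive
  if (stochastic) {
    bin <- function(x, p) stats::rbinom(1, round(max(x, 0) * scale), p) / scale
    rS <- bin(relS, pRel); rA <- bin(relA, pRel)
  } else {
    rS <- relS * pRel; rA <- relA * pRel
  }
  pool@senseActive <- pool@senseActive + rS
  pool@antiActive <- pool@antiActive + rA
  pool@senseInactive <- relS - rS
  pool@antiInactive <- relA - rA
  pool@partials <- pool@partials + dPart

  # destruction of complexes at the peak; material returns to monomers
  pDes <- .pDestroy(rates, tP)
  if (pDes > 0) {
    destroy <- function(x) if (stochastic)
      stats::rbinom(1, round(max(x, 0) * scale), pDes) / scale else x * pDes
    lost <- c(sa = destroy(pool@senseActive), aa = destroy(pool@antiActive),
              si = destroy(pool@senseInactive),
              ai = destroy(pool@antiInactive), pp = destroy(pool@partials))
    pool@senseActive <- pool@senseActive - lost[["sa"]]
    pool@antiActive <- pool@antiActive - lost[["aa"]]
    pool@senseInactive <- pool@senseInactive - lost[["si"]]
    pool@antiInactive <- pool@antiInactive - lost[["ai"]]
    pool@partials <- pool@partials - lost[["pp"]]
    if (!rates@ideal) {
      credit <- function(mon, usage, amount, n = 4) {
        for (id in head(usage[!is.na(usage)], n))
          mon[id] <- mon[id] + amount
        mon
      }
      mon <- credit(pool@monomers, useS, lost[["sa"]] + lost[["si"]])
      mon <- credit(mon, useA, lost[["aa"]] + lost[["ai"]])
      mon <- credit(mon, useS, lost[["pp"]], 3)
      pool@monomers <- mon
    }
  }
  pool
}

#' Run a thermal-oscillation protocol
#'
#' Iterates [stepCycle] over the protocol's cycles. The deterministic
#' variant propagates expected values; the stochastic variant draws
#' molecule-count outcomes from a seeded generator.
#'
#' @param pool initial [SpeciesPool-class].
#' @param protocol a [CycleProtocol-class].
#' @param rates a [MechanisticRates-class].
#' @param stochastic logical (default FALSE).
#' @param seed seed for the stochastic variant.
#' @param scale molecules per nM for the stochastic variant.
#' @return A list: `trajectory` (data.frame cycle, c, cbar, partials;
#'   c and cbar count all tetramer-containing complexes of either sense)
#'   and `pool` (final state).
#' @examples
#' lib <- annotateLibrary(loadStrandLibrary())
#' rates <- mechanisticRates(lib)
#' run <- runProtocol(speciesPool("0000", antiTemplate = 30),
#'                    cycleProtocol(nCycles = 6), rates)
#' run$trajectory
#' @export
runProtocol <- function(pool, protocol, rates, stochastic = FALSE,
                        seed = NULL, scale = 100) {
  .localSeed(seed, function() {
    rows <- list(data.frame(cycle = 0,
                            c = pool@senseActive + pool@senseInactive,
                            cbar = pool@antiActive + pool@antiInactive,
                            partials = pool@partials))
    for (cyc in seq_len(protocol@nCycles)) {
      pool <- stepCycle(pool, protocol, rates, stochastic, scale)
      rows[[cyc + 1L]] <- data.frame(
        cycle = cyc,
        c = pool@senseActive + pool@senseInactive,
        cbar = pool@antiActive + pool@antiInactive,
        partials = pool@partials)
    }
    list(trajectory = do.call(rbind, rows), pool = pool)
  })
}

#' Scan a protocol temperature and report 6-cycle yields
#'
#' Reruns the deterministic simulator over a grid of peak or base
#' temperatures and reports the final tetramer yield together with the
#' underlying templated and spontaneous rates at the base temperature.
#'
#' @param protocol template [CycleProtocol-class].
#' @param rates a [MechanisticRates-class].
#' @param variable `"tPeak"` or `"tBase"`.
#' @param values temperatures to scan, degrees C.
#' @param code meta-sequence (default `"0000"`).
#' @param antiTemplate initial template concentration, nM (default 30).
#' @param monomerConc monomer concentration per strand, nM (default 200).
#' @return data.frame: value, yield (final c, nM), kTemplated (per-cycle
#'   templated gain at the base temperature), kSpont (spontaneous rate,
#'   nM/cycle).
#' @export
temperatureScan <- function(protocol, rates, variable = c("tPeak", "tBase"),
                            values, code = "0000", antiTemplate = 30,
                            monomerConc = 200) {
  variable <- match.arg(variable)
  rows <- lapply(values, function(v) {
    pr <- protocol
    slot(pr, variable) <- v
    pool <- speciesPool(code, monomerConc = monomerConc,
                        antiTemplate = antiTemplate)
    run <- runProtocol(pool, pr, rates)
    occ <- .occupancy(rates, pr@tBase)
    data.frame(value = v,
               yield = run$trajectory$c[nrow(run$trajectory)],
               kTemplated = .templatedPrefactor(rates, pr@tBase) * occ^4,
               kSpont = .spontRate(rates, pr@tBase))
  })
  do.call(rbind, rows)
}
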