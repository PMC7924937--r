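# Seeded generators emulating the statistical structure of gel-quantified
# concentration traces and plate-reader melting curves, so every analysis
# stage is testable without experimental data. Noise is multiplicative
# Gaussian (band intensity scales with concentration) plus an additive
# floor (detection limit), clamped at zero.

#' Noise specification for synthetic traces
#'
#' @slot sigmaRel relative (multiplicative) standard deviation (default 0.10).
#' @slot sigmaAbs additive floor standard deviation, nM (default 1.0).
#' @export
setClass("NoiseSpec",
  representation(sigmaRel = "numeric", sigmaAbs = "numeric"),
  validity = function(object) {
    if (object@sigmaRel < 0 || object@sigmaAbs < 0)
      return("noise standard deviations must be nonnegative")
    TRUE
  })

#' Construct a noise specification
#'
#' @param sigmaRel relative standard deviation.
#' @param sigmaAbs additive standard deviation, nM.
#' @return A [NoiseSpec-class].
#' @examples
#' noiseSpec()            # 10% multiplicative + 1 nM floor
#' noiseSpec(0, 0)        # noiseless
#' @export
noiseSpec <- function(sigmaRel = 0.10, sigmaAbs = 1.0) {
  new("NoiseSpec", sigmaRel = sigmaRel, sigmaAbs = sigmaAbs)
}

.applyNoise <- function(x, noise) {
  y <- x * (1 + stats::rnorm(length(x), 0, noise@sigmaRel)) +
    stats::rnorm(length(x), 0, noise@sigmaAbs)
  pmax(y, 0)
}

#' Generate synthetic per-cycle amplification traces
#'
#' Samples closed-form cross-catalytic trajectories (c0 = 0) at integer
#' cycles for several initial template concentrations, applies the noise
#' model, and clamps at zero. Deterministic under a fixed seed.
#'
#' @param model a [CrossCatalyticModel-class].
#' @param cbar0 initial template concentrations, nM.
#' @param nCycles number of cycles (sampled at 0..nCycles).
#' @param noise a [NoiseSpec-class].
#' @param replicates replicates per template concentration.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return data.frame: cycle, concentration_nM, series, c_bar0_nM,
#'   replicate.
#' @examples
#' m <- crossCatalyticModel(0.16, 0.4)
#' tr <- genAmplificationTraces(m, seed = 1)
#' head(tr)
#' @export
genAmplificationTraces <- function(model, cbar0 = c(0, 5, 15, 30, 45),
                                   nCycles = 6, noise = noiseSpec(),
                                   replicates = 1, seed = NULL) {
  .localSeed(seed, function() {
    out <- list()
    for (cb in cbar0) {
      clean <- closedForm(model, 0, cb, 0:nCycles)
      for (r in seq_len(replicates)) {
        out[[length(out) + 1L]] <- data.frame(
          cycle = clean$cycle,
          concentration_nM = .applyNoise(clean$c, noise),
          series = sprintf("cbar0=%g_rep%d", cb, r),
          c_bar0_nM = cb, replicate = r, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Generate a synthetic serial-transfer trace
#'
#' The survivor series (growth plus dilution every few cycles) and the
#' fading control lacking fresh monomers, with noise.
#'
#' @param model a [CrossCatalyticModel-class].
#' @param spec a [SerialTransferSpec-class].
#' @param cbar0 initial template concentration, nM.
#' @param noise a [NoiseSpec-class].
#' @param seed RNG seed.
#' @return data.frame: cycle, concentration_nM, series
#'   ("transfer"/"control"); the control column reports cbar (the diluted
#'   template), the transfer series reports c (the growing replicate pool).
#' @export
genSerialTransferTrace <- function(model, spec = serialTransferSpec(),
                                   cbar0 = 30, noise = noiseSpec(),
                                   seed = NULL) {
  .localSeed(seed, function() {
    surv <- simulateSerialTransfer(model, spec, cbar0)
    ctrlSpec <- spec
    ctrlSpec@monomerReplenished <- FALSE
    ctrl <- simulateSerialTransfer(model, ctrlSpec, cbar0)
    rbind(
      data.frame(cycle = surv$cycle,
                 concentration_nM = .applyNoise(surv$c, noise),
                 series = "transfer", stringsAsFactors = FALSE),
      data.frame(cycle = ctrl$cycle,
                 concentration_nM = .applyNoise(ctrl$cbar, noise),
                 series = "control", stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic melting curve
#'
#' Maps the two-state unbound fraction of a duplex with the given (dH, dS)
#' through linear lower/upper baselines and adds noise.
#'
#' @param dH duplex enthalpy, kcal/mol.
#' @param dS duplex entropy, cal/(mol K) (already salt-corrected).
#' @param conditions [IonicConditions-class] (strand concentration).
#' @param temperatures temperature grid, degrees C.
#' @param baselines list with `lower` and `upper`, each c(intercept, slope)
#'   of the baseline signal.
#' @param noise a [NoiseSpec-class]; `sigmaRel` acts on the signal,
#'   `sigmaAbs` in signal units (use small values, the signal is O(1)).
#' @param seed RNG seed.
#' @return data.frame: temperature_C, signal.
#' @examples
#' mc <- genMeltingCurve(-105, -290, seed = 1)
#' @export
genMeltingCurve <- function(dH, dS, conditions = ionicConditions(),
                            temperatures = seq(15, 90, by = 1),
                            baselines = list(lower = c(0.05, 0),
                                             upper = c(1, 0)),
                            noise = noiseSpec(0, 0), seed = NULL) {
  .localSeed(seed, function() {
    d <- new("DuplexThermo", dH = dH, dS = dS, conditions = conditions,
             top = "", bottom = "", nUnparameterized = 0L)
    u <- unboundFraction(d, temperatures)
    lo <- baselines$lower[1] + baselines$lower[2] * temperatures
    hi <- baselines$upper[1] + baselines$upper[2] * temperatures
    sig <- (1 - u) * lo + u * hi
    sig <- sig * (1 + stats::rnorm(length(sig), 0, noise@sigmaRel)) +
      stats::rnorm(length(sig), 0, noise@sigmaAbs)
    data.frame(temperature_C = temperatures, signal = sig)
  })
}

#' Generate endpoint-yield tables for defective strand sets
#'
#' Emulates the six-cycle endpoint comparison across defect patterns. The
#' default means are the full-set endpoint (37 nM), the single-defect
#' endpoint (14 nM), and the double-defect endpoints from the independence
#' arithmetic 37 x 0.4^2 (~5.9 nM; the non-adjacent double defect behaves
#' like the untemplated reference and defaults to the same mean).
#'
#' @param noise a [NoiseSpec-class].
#' @param replicates replicates per pattern.
#' @param means named numeric of endpoint means per defect pattern, nM.
#' @param seed RNG seed.
#' @return data.frame: pattern, replicate, endpoint_nM.
#' @examples
#' genDefectEndpoints(noiseSpec(0, 0))
#' @export
genDefectEndpoints <- function(noise = noiseSpec(), replicates = 1,
                               means = c("++++" = 37, "+++-" = 14,
                                         "++--" = 37 * 0.16,
                                         "+-+-" = 37 * 0.16),
                               seed = NULL) {
  .localSeed(seed, function() {
    out <- expand.grid(pattern = names(means),
                       replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
    out$endpoint_nM <- .applyNoise(means[out$pattern], noise)
    out
  })
}

#' Generate a random strand pool
#'
#' Uniform random ACGT strands of the stated length, the negative-control
#' material for design-validation tests (a random pool shares no
#' information domain).
#'
#' @param nStrands number of strands (default 8).
#' @param length strand length, nt (default 84).
#' @param seed RNG seed.
#' @return A [Biostrings::DNAStringSet] named R1..Rn.
#' @examples
#' genRandomPool(seed = 1)
#' @export
genRandomPool <- function(nStrands = 8, length = 84, seed = NULL) {
  .localSeed(seed, function() {
    seqs <- vapply(seq_len(nStrands), function(i)
      paste(sample(.BASES, length, replace = TRUE), collapse = ""),
      character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs,
                                             paste0("R", seq_len(nStrands))))
  })
}
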