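# Nearest-neighbor duplex thermodynamics: two-state dH/dS sums with
# internal and terminal mismatch parameters, mixed Na+/Mg2+ salt correction,
# melting temperatures, unbound fractions and melting-curve fitting.

.sodiumEquivalent <- function(cond) {
  # von Ahsen sodium-equivalent for mixed monovalent/Mg2+ buffers, in mol/L
  (cond@monovalent + 120 * sqrt(cond@divalentMg)) / 1000
}

.saltEntropyCorrection <- function(nbp, cond) {
  naeq <- .sodiumEquivalent(cond)
  if (naeq <= 0) stop("salt correction needs a positive cation concentration")
  0.368 * (nbp - 1) * log(naeq)
}

#' @noRd
.complementVec <- function(chars) unname(.COMPLEMENT[chars])

# Batch NN sum for one top strand against many aligned bottom strands.
# `top` is a character vector of bases 5'->3'; `botMat` a character matrix
# (one row per bottom strand, 3'->5' so column i pairs top[i]).
# Terminal mismatched pairs use the terminal-mismatch table in place of the
# flanking stack; NN steps with two non-WC pairs (tandem mismatches) have no
# published parameters and contribute no stacking.
.stackEnergyBatch <- function(top, botMat) {
  n <- length(top)
  m <- nrow(botMat)
  topComp <- .complementVec(top)
  dh <- numeric(m)
  ds <- numeric(m)
  nUnparam <- integer(m)

  stepDH <- stepDS <- matrix(0, m, n - 1L)
  for (j in seq_len(n - 1L)) {
    keys <- paste0(top[j], top[j + 1L], "/", botMat[, j], botMat[, j + 1L])
    vdh <- .NN_STACK$dh[keys]
    miss <- is.na(vdh)
    stepDH[, j] <- ifelse(miss, 0, vdh)
    stepDS[, j] <- ifelse(miss, 0, .NN_STACK$ds[keys])
    nUnparam <- nUnparam + as.integer(miss)
  }

  leftMM <- botMat[, 1L] != topComp[1L]
  if (any(leftMM)) {
    # step 1 is replaced by the terminal-mismatch parameter (reversed key)
    idx <- which(leftMM)
    nUnparam[idx] <- nUnparam[idx] -
      as.integer(stepDH[idx, 1L] == 0 & stepDS[idx, 1L] == 0)
    nUnparam[idx] <- pmax(nUnparam[idx], 0L)
    stepDH[idx, 1L] <- 0
    stepDS[idx, 1L] <- 0
    keys <- paste0(botMat[idx, 2L], botMat[idx, 1L], "/", top[2L], top[1L])
    vdh <- .NN_TERM$dh[keys]
    vds <- .NN_TERM$ds[keys]
    dh[idx] <- dh[idx] + ifelse(is.na(vdh), 0, vdh)
    ds[idx] <- ds[idx] + ifelse(is.na(vds), 0, vds)
  }
  rightMM <- botMat[, n] != topComp[n]
  if (any(rightMM)) {
    idx <- which(rightMM)
    nUnparam[idx] <- pmax(nUnparam[idx] -
      as.integer(stepDH[idx, n - 1L] == 0 & stepDS[idx, n - 1L] == 0), 0L)
    stepDH[idx, n - 1L] <- 0
    stepDS[idx, n - 1L] <- 0
    keys <- paste0(top[n - 1L], top[n], "/", botMat[idx, n - 1L], botMat[idx, n])
    vdh <- .NN_TERM$dh[keys]
    vds <- .NN_TERM$ds[keys]
    dh[idx] <- dh[idx] + ifelse(is.na(vdh), 0, vdh)
    ds[idx] <- ds[idx] + ifelse(is.na(vds), 0, vds)
  }

  dh <- dh + rowSums(stepDH)
  ds <- ds + rowSums(stepDS)

  # initiation: general term plus per-end A/T vs G/C penalties
  ends <- c(top[1L], top[n])
  nAT <- sum(ends %in% c("A", "T"))
  nGC <- 2L - nAT
  dh <- dh + .NN_INIT[1] + nAT * .NN_INIT_AT[1] + nGC * .NN_INIT_GC[1]
  ds <- ds + .NN_INIT[2] + nAT * .NN_INIT_AT[2] + nGC * .NN_INIT_GC[2]

  list(dh = dh, ds = ds, nUnparam = nUnparam)
}

#' Nearest-neighbor thermodynamics of a DNA duplex
#'
#' Sums nearest-neighbor dH/dS steps (Watson-Crick and single internal
#' mismatches), duplex initiation and terminal penalties; terminal
#' mismatched base pairs use terminal-mismatch parameters. The entropy is
#' salt-corrected to the supplied buffer via the sodium-equivalent
#' correction. Steps with two non-Watson-Crick pairs (tandem mismatches)
#' carry no published parameters and contribute no stacking; their count is
#' recorded in the result.
#'
#' @param top top strand, 5'->3'.
#' @param bottom bottom strand given 3'->5', aligned antiparallel against
#'   `top` so position i pairs position i; mismatches permitted. Default:
#'   the perfect complement of `top`.
#' @param conditions an [IonicConditions-class]; defaults to the replication
#'   buffer (150 mM NaCl, 20 mM MgCl2, 400 nM total strands).
#' @return A [DuplexThermo-class] object.
#' @examples
#' d0 <- duplexThermo("AGTGGGTAATAATGA")
#' deltaG(d0)               # kcal/mol at 37 C
#' meltingTemperature(d0)   # degrees C
#' @export
duplexThermo <- function(top, bottom = NULL,
                         conditions = ionicConditions()) {
  top <- toupper(as.character(top))
  topv <- strsplit(top, "")[[1]]
  if (length(topv) < 2L) stop("duplex must have at least 2 base pairs")
  if (any(!topv %in% .BASES)) stop("top strand contains non-ACGT characters")
  if (is.null(bottom)) {
    botv <- .complementVec(topv)
    bottom <- paste(botv, collapse = "")
  } else {
    bottom <- toupper(as.character(bottom))
    botv <- strsplit(bottom, "")[[1]]
    if (length(botv) != length(topv))
      stop("top and bottom strands must have equal length")
    if (any(!botv %in% .BASES)) stop("bottom strand contains non-ACGT characters")
  }
  e <- .stackEnergyBatch(topv, matrix(botv, nrow = 1L))
  ds <- e$ds[1] + .saltEntropyCorrection(length(topv), conditions)
  new("DuplexThermo", dH = e$dh[1], dS = ds, conditions = conditions,
      top = top, bottom = bottom, nUnparameterized = e$nUnparam[1])
}

#' @describeIn deltaG free energy dH - T*dS/1000 at `tempC`.
#' @export
setMethod("deltaG", "DuplexThermo", function(object, tempC = 37) {
  object@dH - (tempC + 273.15) * object@dS / 1000
})

#' @describeIn meltingTemperature two-state Tm for a non-self-complementary
#'   duplex at equal strand concentrations:
#'   Tm = 1000*dH / (dS + R*ln(CT/4)) - 273.15.
#' @export
setMethod("meltingTemperature", "DuplexThermo", function(object, ...) {
  ct <- object@conditions@totalStrandConc
  denom <- object@dS + .GAS_CONSTANT * log(ct / 4)
  if (denom >= 0)
    stop("unphysical parameters: dS + R*ln(CT/4) must be negative")
  1000 * object@dH / denom - 273.15
})

#' @describeIn unboundFraction solves the bimolecular two-state equilibrium
#'   A + B = AB at equal strand concentrations for the unbound fraction.
#' @export
setMethod("unboundFraction", "DuplexThermo", function(object, tempC) {
  tK <- tempC + 273.15
  dG <- object@dH - tK * object@dS / 1000
  K <- exp(-dG * 1000 / (.GAS_CONSTANT * tK))
  a <- K * object@conditions@totalStrandConc / 2
  u <- 2 / (1 + sqrt(1 + 4 * a))   # stable form of (-1 + sqrt(1+4a))/(2a)
  pmin(pmax(u, 0), 1)
})

# temperature (C) at which the unbound fraction equals u
.temperatureAtUnbound <- function(object, u) {
  ct <- object@conditions@totalStrandConc
  K <- (1 - u) / ((ct / 2) * u^2)
  1000 * object@dH / (object@dS - .GAS_CONSTANT * log(K)) - 273.15
}

#' Two-state melting curve of a duplex
#'
#' @param object a [DuplexThermo-class].
#' @param temperatures temperature grid, degrees C.
#' @return A [MeltingCurve-class] with the unbound fraction on the grid, the
#'   melting temperature and the 10--90% transition width.
#' @examples
#' meltingCurve(duplexThermo("AGTGGGTAATAATGA"), seq(20, 90, by = 0.5))
#' @export
meltingCurve <- function(object, temperatures = seq(10, 95, by = 0.25)) {
  temperatures <- sort(temperatures)
  u <- unboundFraction(object, temperatures)
  new("MeltingCurve", temperatures = temperatures, unboundFraction = u,
      tm = meltingTemperature(object),
      width = .temperatureAtUnbound(object, 0.9) -
              .temperatureAtUnbound(object, 0.1))
}

#' Fit a two-state melting transition with linear baselines
#'
#' Models the measured signal as a linear lower baseline below the
#' transition and a linear upper baseline above it, mixed by the two-state
#' unbound fraction: signal(T) = (1-u)(al + bl*T) + u(au + bu*T), with u
#' parameterized by (dH, Tm) at the stated strand concentration. Fitting is
#' by Levenberg-Marquardt least squares with multi-start over the enthalpy.
#'
#' @param data a data.frame whose first two columns are temperature
#'   (degrees C) and signal, e.g. as read from a two-column TSV.
#' @param conditions [IonicConditions-class] giving the strand concentration
#'   the curve was measured at.
#' @return A list with elements `curve` (a [MeltingCurve-class] on the data
#'   grid), `thermo` (the [DuplexThermo-class]-equivalent (dH, dS) estimate),
#'   `tm`, `width`, and `fit` (the `nls` object).
#' @examples
#' d <- duplexThermo("AGTGGGTAATAATGA")
#' tc <- seq(20, 85, by = 1)
#' sig <- unboundFraction(d, tc)
#' fitMeltingCurve(data.frame(temperature_C = tc, signal = sig))$tm
#' @export
fitMeltingCurve <- function(data, conditions = ionicConditions()) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  tc <- as.numeric(data[[1]])
  y <- as.numeric(data[[2]])
  ok <- is.finite(tc) & is.finite(y)
  tc <- tc[ok]; y <- y[ok]
  if (length(tc) < 15) stop("need at least 15 points spanning the transition")
  rng <- diff(range(y))
  if (rng < .Machine$double.eps^0.5)
    stop("no transition detected: signal is constant")
  lin <- stats::lm(y ~ tc)
  r2 <- 1 - sum(stats::resid(lin)^2) / sum((y - mean(y))^2)
  if (r2 > 0.995)
    stop("no transition detected: data are consistent with a single baseline")

  ct <- conditions@totalStrandConc
  yn <- (y - min(y)) / rng
  # orient so the normalized signal increases with temperature
  if (stats::cor(tc, yn) < 0) yn <- 1 - yn
  tm0 <- tc[which.min(abs(yn - 0.5))]

  nlo <- max(3L, floor(length(tc) * 0.15))
  loIdx <- seq_len(nlo)
  hiIdx <- seq(length(tc) - nlo + 1L, length(tc))
  baseLo <- stats::coef(stats::lm(y[loIdx] ~ tc[loIdx]))
  baseHi <- stats::coef(stats::lm(y[hiIdx] ~ tc[hiIdx]))

  model <- function(dH, tm, al, bl, au, bu, tc) {
    dS <- 1000 * dH / (tm + 273.15) - .GAS_CONSTANT * log(ct / 4)
    tK <- tc + 273.15
    K <- exp(-(dH * 1000 - tK * dS) / (.GAS_CONSTANT * tK))
    a <- K * ct / 2
    u <- 2 / (1 + sqrt(1 + 4 * a))
    (1 - u) * (al + bl * tc) + u * (au + bu * tc)
  }

  best <- NULL
  for (dH0 in c(-60, -100, -150)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model(dH, tm, al, bl, au, bu, tc),
        start = list(dH = dH0, tm = tm0, al = baseLo[1], bl = baseLo[2],
                     au = baseHi[1], bu = baseHi[2]),
        lower = c(dH = -400, tm = min(tc) - 20, al = -Inf, bl = -Inf,
                  au = -Inf, bu = -Inf),
        upper = c(dH = -5, tm = max(tc) + 20, al = Inf, bl = Inf,
                  au = Inf, bu = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) stop("melting-curve fit failed to converge")
  cf <- stats::coef(best$fit)
  dS <- 1000 * cf[["dH"]] / (cf[["tm"]] + 273.15) - .GAS_CONSTANT * log(ct / 4)
  thermo <- new("DuplexThermo", dH = cf[["dH"]], dS = dS,
                conditions = conditions, top = "", bottom = "",
                nUnparameterized = 0L)
  list(curve = meltingCurve(thermo, sort(tc)),
       thermo = thermo,
       tm = cf[["tm"]],
       width = .temperatureAtUnbound(thermo, 0.9) -
               .temperatureAtUnbound(thermo, 0.1),
       fit = best$fit)
}
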