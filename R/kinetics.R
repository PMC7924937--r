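# The cross-catalytic growth model: closed-form trajectories, joint fitting
# to per-cycle traces, initial-velocity analysis, serial-transfer modeling
# and sigmoid fitting of sedimentation traces.

#' Closed-form trajectories of the cross-catalytic model
#'
#' Solves dc/dt = k*cbar + k0, dcbar/dt = k*c + k0 in closed form via the
#' sum s = c + cbar and difference d = c - cbar:
#' s(t) = (s0 + 2 k0/k) e^(kt) - 2 k0/k (or s0 + 2 k0 t for k = 0),
#' d(t) = d0 e^(-kt).
#'
#' @param model a [CrossCatalyticModel-class].
#' @param c0 initial template-sense concentration, nM.
#' @param cbar0 initial complement concentration, nM.
#' @param t cycle numbers (continuous time in cycle units, >= 0).
#' @return data.frame with columns `cycle`, `c`, `cbar` (nM).
#' @examples
#' m <- crossCatalyticModel(k = 0.16, k0 = 0.4)
#' closedForm(m, c0 = 0, cbar0 = 30, t = 0:6)
#' @export
closedForm <- function(model, c0, cbar0, t) {
  if (c0 < 0 || cbar0 < 0) stop("initial concentrations must be nonnegative")
  if (any(t < 0)) stop("t must be nonnegative")
  k <- model@k; k0 <- model@k0
  s0 <- c0 + cbar0; d0 <- c0 - cbar0
  s <- if (k > 0) (s0 + 2 * k0 / k) * exp(k * t) - 2 * k0 / k
       else s0 + 2 * k0 * t
  d <- d0 * exp(-k * t)
  data.frame(cycle = t, c = (s + d) / 2, cbar = (s - d) / 2)
}

#' Initial reaction velocity
#'
#' Model-derived initial velocity dc/dt at t = 0 with c0 = 0:
#' v0 = k * cbar0 + k0, affine in the initial template concentration with
#' slope k and intercept k0.
#'
#' @param model a [CrossCatalyticModel-class].
#' @param cbar0 initial template concentration(s), nM.
#' @return Initial velocity, nM/cycle; vectorized over `cbar0`.
#' @examples
#' initialVelocity(crossCatalyticModel(0.16, 0.4), 30)   # 5.2
#' @export
initialVelocity <- function(model, cbar0) {
  model@k * cbar0 + model@k0
}

.localSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr())
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr()
}

#' Jointly fit the cross-catalytic model to amplification traces
#'
#' Least-squares fit of shared (k, k0) across per-cycle traces recorded at
#' different initial template concentrations, with c0 = 0. Points above a
#' configurable fraction of the per-strand total concentration are excluded
#' (the model does not account for monomer-depletion saturation).
#' Uncertainties come from a seeded bootstrap over traces.
#'
#' @param traces data.frame with columns `cycle`, `concentration_nM`,
#'   `c_bar0_nM`, and optionally `series` (trace id; defaults to
#'   `c_bar0_nM` x `replicate` if present).
#' @param strandTotal per-strand total concentration, nM (default 200).
#' @param saturationFraction exclusion threshold as a fraction of
#'   `strandTotal` (default 0.5).
#' @param nBoot bootstrap replicates (default 200).
#' @param seed seed for the bootstrap resampling.
#' @return A list: `model` ([CrossCatalyticModel-class]), `kCI` and `k0CI`
#'   (95% percentile intervals), `nPoints`, `nExcluded`, `residuals`,
#'   `bootstrap` (matrix of resampled estimates).
#' @export
fitCrossCatalytic <- function(traces, strandTotal = 200,
                              saturationFraction = 0.5, nBoot = 200,
                              seed = NULL) {
  stopifnot(all(c("cycle", "concentration_nM", "c_bar0_nM") %in%
                  names(traces)))
  if (is.null(traces$series)) {
    traces$series <- if (!is.null(traces$replicate))
      paste(traces$c_bar0_nM, traces$replicate, sep = "_")
    else as.character(traces$c_bar0_nM)
  }
  keep <- traces$concentration_nM <= saturationFraction * strandTotal
  nExcluded <- sum(!keep)
  dat <- traces[keep, , drop = FALSE]
  if (nrow(dat) < 3) stop("fewer than 3 usable points below saturation")

  sse <- function(par, d) {
    k <- par[1]; k0 <- par[2]
    if (k < 0 || k0 < 0) return(Inf)
    pred <- if (k > 0)
      ((d$c_bar0_nM + 2 * k0 / k) * exp(k * d$cycle) - 2 * k0 / k -
         d$c_bar0_nM * exp(-k * d$cycle)) / 2
    else k0 * d$cycle
    sum((pred - d$concentration_nM)^2)
  }

  fitOnce <- function(d) {
    best <- NULL
    for (k0s in c(0.05, 0.2, 0.4, 1.6)) {
      for (ks in c(0.02, 0.08, 0.16, 0.32, 0.64)) {
        o <- stats::optim(c(ks, k0s), sse, d = d, method = "L-BFGS-B",
                          lower = c(1e-8, 0), upper = c(10, 100))
        if (is.null(best) || o$value < best$value) best <- o
      }
    }
    best
  }

  best <- fitOnce(dat)
  k <- best$par[1]; k0 <- best$par[2]
  seriesIds <- unique(dat$series)
  boot <- if (nBoot > 0) .localSeed(seed, function() {
    t(vapply(seq_len(nBoot), function(i) {
      pick <- sample(seriesIds, length(seriesIds), replace = TRUE)
      db <- do.call(rbind, lapply(pick, function(s)
        dat[dat$series == s, , drop = FALSE]))
      o <- stats::optim(best$par, sse, d = db, method = "L-BFGS-B",
                        lower = c(1e-8, 0), upper = c(10, 100))
      o$par
    }, numeric(2)))
  }) else matrix(numeric(0), 0, 2)
  res <- vapply(seq_len(nrow(dat)), function(i) {
    cf <- closedForm(crossCatalyticModel(k, k0), 0, dat$c_bar0_nM[i],
                     dat$cycle[i])
    dat$concentration_nM[i] - cf$c
  }, numeric(1))
  list(model = crossCatalyticModel(k, k0),
       kCI = if (nBoot > 0)
         stats::quantile(boot[, 1], c(0.025, 0.975), names = FALSE)
       else c(NA_real_, NA_real_),
       k0CI = if (nBoot > 0)
         stats::quantile(boot[, 2], c(0.025, 0.975), names = FALSE)
       else c(NA_real_, NA_real_),
       nPoints = nrow(dat), nExcluded = nExcluded,
       residuals = res, bootstrap = boot)
}

#' Simulate a serial-transfer experiment
#'
#' Alternates closed-form cross-catalytic growth segments with a
#' multiplicative dilution of the product species every
#' `cyclesPerTransfer` cycles. If `monomerReplenished` is `FALSE` the
#' reaction cannot grow (no fresh monomers: k and k0 are disabled after the
#' start) and the trace fades by the dilution factor per transfer.
#' Concentrations are recorded at every integer cycle, pre-dilution at the
#' transfer cycles.
#'
#' @param model a [CrossCatalyticModel-class].
#' @param spec a [SerialTransferSpec-class].
#' @param cbar0 initial template concentration, nM.
#' @param c0 initial replicate concentration, nM (default 0).
#' @return data.frame with columns `cycle`, `c`, `cbar`.
#' @examples
#' m <- crossCatalyticModel(0.16, 0.4)
#' simulateSerialTransfer(m, serialTransferSpec(dilution = 0.43), cbar0 = 30)
#' @export
simulateSerialTransfer <- function(model, spec, cbar0, c0 = 0) {
  grow <- if (spec@monomerReplenished) model else crossCatalyticModel(0, 0)
  cp <- spec@cyclesPerTransfer
  st <- c(c = c0, cbar = cbar0)
  rows <- list(data.frame(cycle = 0, c = c0, cbar = cbar0))
  for (tr in seq_len(spec@nTransfers)) {
    seg <- closedForm(grow, st[["c"]], st[["cbar"]], seq_len(cp))
    seg$cycle <- seg$cycle + (tr - 1) * cp
    rows[[length(rows) + 1L]] <- seg
    st <- c(c = seg$c[cp] * spec@dilution, cbar = seg$cbar[cp] * spec@dilution)
  }
  do.call(rbind, rows)
}

#' Fit the serial-transfer dilution factor
#'
#' One-dimensional least squares over the dilution factor in (0, 1], with
#' the growth rates (k, k0) held fixed at previously fitted values.
#'
#' @param trace data.frame with columns `cycle` and `c` (or
#'   `concentration_nM`), as produced by [simulateSerialTransfer] or the
#'   synthetic generator.
#' @param model the fixed [CrossCatalyticModel-class].
#' @param spec a [SerialTransferSpec-class]; its `dilution` slot is ignored
#'   (it is the free parameter).
#' @param cbar0 initial template concentration, nM.
#' @param c0 initial replicate concentration, nM.
#' @return A list: `dilution` (estimate), `sse`, `fit` (the `optimize`
#'   result).
#' @export
fitDilutionFactor <- function(trace, model, spec, cbar0, c0 = 0) {
  y <- if (!is.null(trace$c)) trace$c else trace$concentration_nM
  if (is.null(y)) stop("trace must have a 'c' or 'concentration_nM' column")
  obj <- function(d) {
    sp <- spec; sp@dilution <- d
    sim <- simulateSerialTransfer(model, sp, cbar0, c0)
    pred <- sim$c[match(trace$cycle, sim$cycle)]
    if (anyNA(pred)) return(Inf)
    sum((pred - y)^2)
  }
  o <- stats::optimize(obj, interval = c(0.01, 1), tol = 1e-6)
  if (!is.finite(o$objective))
    stop("dilution-factor fit did not converge (cycles do not align?)")
  list(dilution = o$minimum, sse = o$objective, fit = o)
}

#' Fit a three-parameter logistic to a time trace
#'
#' Fits value(t) = b + L / (1 + exp(-(t - t0)/w)) and reports the relative
#' concentration increase: amplitude = (plateau - first-frame value) /
#' first-frame value, so a flat trace has amplitude 0 (and c/c0 = 1 +
#' amplitude).
#'
#' @param series data.frame whose first two columns are time and value.
#' @return A list: `amplitude`, `midpoint` (t0), `slope` (1/w), `flat`
#'   (TRUE when the data showed no usable rise), `fit`.
#' @export
fitSigmoid <- function(series) {
  stopifnot(is.data.frame(series), ncol(series) >= 2)
  t <- as.numeric(series[[1]]); y <- as.numeric(series[[2]])
  if (length(t) < 6) stop("need at least 6 points")
  rng <- diff(range(y))
  scale <- max(abs(y), 1e-12)
  if (rng < 1e-6 * scale)
    return(list(amplitude = 0, midpoint = NA_real_, slope = NA_real_,
                flat = TRUE, fit = NULL))
  t0 <- t[which.min(abs(y - (min(y) + rng / 2)))]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + L / (1 + exp(-(t - t0) / w)),
                      start = list(b = min(y), L = rng, t0 = t0,
                                   w = diff(range(t)) / 10),
                      lower = c(b = -Inf, L = 0, t0 = min(t) - diff(range(t)),
                                w = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(amplitude = 0, midpoint = NA_real_, slope = NA_real_,
                flat = TRUE, fit = NULL))
  cf <- stats::coef(fit)
  first <- cf[["b"]] + cf[["L"]] / (1 + exp(-(t[1] - cf[["t0"]]) / cf[["w"]]))
  plateau <- cf[["b"]] + cf[["L"]]
  list(amplitude = (plateau - first) / first,
       midpoint = cf[["t0"]], slope = 1 / cf[["w"]],
       flat = FALSE, fit = fit)
}
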