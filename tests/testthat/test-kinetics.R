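# Cross-catalytic growth: closed form vs numerical integration, joint
# fitting, serial transfer, and sigmoid fitting.

test_that("closed form matches a small-step numerical integration", {
  library(deSolve)
  rhs <- function(t, y, p) list(c(p$k * y[2] + p$k0, p$k * y[1] + p$k0))
  set.seed(3)
  for (i in 1:5) {
    k <- runif(1, 0, 0.5); k0 <- runif(1, 0, 1)
    c0 <- runif(1, 0, 20); cb0 <- runif(1, 0, 50)
    t <- seq(0, 6, by = 0.5)
    num <- deSolve::ode(c(c0, cb0), t, rhs, list(k = k, k0 = k0),
                        method = "ode45", atol = 1e-10, rtol = 1e-10)
    cf <- closedForm(crossCatalyticModel(k, k0), c0, cb0, t)
    expect_equal(cf$c, unname(num[, 2]), tolerance = 1e-6)
    expect_equal(cf$cbar, unname(num[, 3]), tolerance = 1e-6)
  }
})

test_that("closed-form limits and symmetries hold", {
  m0 <- crossCatalyticModel(0, 0)
  cf <- closedForm(m0, 3, 7, 0:5)
  expect_equal(cf$c, rep(3, 6))
  expect_equal(cf$cbar, rep(7, 6))
  # equal starting concentrations stay equal (symmetry)
  m <- crossCatalyticModel(0.2, 0.3)
  cf2 <- closedForm(m, 10, 10, seq(0, 8, by = 0.25))
  expect_equal(cf2$c, cf2$cbar, tolerance = 1e-12)
  # no spontaneous creation from an empty pool
  cf3 <- closedForm(crossCatalyticModel(0.3, 0), 0, 0, 0:10)
  expect_true(all(cf3$c == 0 & cf3$cbar == 0))
  # difference decays at rate k; sum grows by e^k per cycle when k0 = 0
  mk <- crossCatalyticModel(0.16, 0)
  cf4 <- closedForm(mk, 2, 30, 0:6)
  d <- cf4$c - cf4$cbar
  expect_equal(d, (2 - 30) * exp(-0.16 * (0:6)), tolerance = 1e-12)
  s <- cf4$c + cf4$cbar
  expect_equal(s[-1] / s[-7], rep(exp(0.16), 6), tolerance = 1e-12)
  expect_error(closedForm(m, -1, 5, 0:3), "nonnegative")
  expect_error(closedForm(m, 0, 5, -1), "nonnegative")
})

test_that("initial velocity is affine in the template concentration", {
  m <- crossCatalyticModel(0.16, 0.4)
  expect_equal(initialVelocity(m, 30), 5.2, tolerance = 1e-12)
  expect_equal(initialVelocity(m, 0), 0.4)
  cb <- c(0, 5, 15, 30, 45)
  v <- initialVelocity(m, cb)
  expect_equal(unname(stats::coef(stats::lm(v ~ cb))), c(0.4, 0.16),
               tolerance = 1e-9)
  # finite difference on the closed form at t -> 0 agrees
  h <- 1e-6
  fd <- (closedForm(m, 0, 30, h)$c - 0) / h
  expect_equal(fd, initialVelocity(m, 30), tolerance = 1e-4)
})

test_that("joint fitting recovers (k, k0) exactly from noiseless traces", {
  set.seed(5)
  for (i in 1:4) {
    k <- runif(1, 0.05, 0.5); k0 <- runif(1, 0.05, 1)
    m <- crossCatalyticModel(k, k0)
    tr <- genAmplificationTraces(m, c(0, 10, 30), nCycles = 5,
                                 noise = noiseSpec(0, 0))
    fit <- fitCrossCatalytic(tr, nBoot = 0)
    expect_equal(fit$model@k, k, tolerance = 1e-4)
    expect_equal(fit$model@k0, k0, tolerance = 1e-4)
  }
})

test_that("joint fitting recovers rates from noisy replicated traces", {
  m <- crossCatalyticModel(0.16, 0.4)
  tr <- genAmplificationTraces(m, c(0, 5, 15, 30, 45), 6, noiseSpec(),
                               replicates = 4, seed = 21)
  fit <- fitCrossCatalytic(tr, nBoot = 50, seed = 22)
  expect_lt(abs(fit$model@k - 0.16) / 0.16, 0.10)
  expect_equal(fit$nPoints, 5 * 4 * 7)
  expect_true(fit$kCI[1] <= fit$kCI[2])
})

test_that("a template-free trace leaves k weakly identified but reported", {
  m <- crossCatalyticModel(0.16, 0.4)
  tr <- genAmplificationTraces(m, 0, 6, noiseSpec(), replicates = 3,
                               seed = 31)
  fit <- fitCrossCatalytic(tr, nBoot = 50, seed = 32)
  expect_true(is.finite(fit$model@k))
  expect_length(fit$kCI, 2L)
  expect_equal(dim(fit$bootstrap), c(50L, 2L))
})

test_that("too few usable points is an error", {
  tr <- data.frame(cycle = 0:6, concentration_nM = rep(300, 7),
                   c_bar0_nM = 30)
  expect_error(fitCrossCatalytic(tr), "fewer than 3")
})

test_that("serial transfer reduces to the closed form without dilution", {
  m <- crossCatalyticModel(0.16, 0.4)
  spec <- serialTransferSpec(dilution = 1, nTransfers = 4)
  st <- simulateSerialTransfer(m, spec, 30)
  cf <- closedForm(m, 0, 30, st$cycle)
  expect_equal(st$c, cf$c, tolerance = 1e-9)
})

test_that("without fresh monomers the trace fades geometrically", {
  m <- crossCatalyticModel(0.16, 0.4)
  spec <- serialTransferSpec(dilution = 0.5, nTransfers = 6,
                             monomerReplenished = FALSE)
  st <- simulateSerialTransfer(m, spec, 32)
  ends <- st$cbar[st$cycle %in% (3 * (1:6))]
  expect_equal(ends, 32 * 0.5^(0:5), tolerance = 1e-9)
})

test_that("growth balancing the dilution yields a level trace", {
  d <- 0.62
  k <- -log(d) / 3        # e^(3k) * d = 1
  m <- crossCatalyticModel(k, 0)
  spec <- serialTransferSpec(dilution = d, nTransfers = 5)
  st <- simulateSerialTransfer(m, spec, 10, c0 = 10)
  ends <- st$c[st$cycle %in% (3 * (1:5))]
  expect_equal(ends, rep(ends[1], 5), tolerance = 1e-9)
})

test_that("dilution-factor fitting recovers the generating value", {
  m <- crossCatalyticModel(0.16, 0.4)
  spec <- serialTransferSpec(dilution = 0.43, nTransfers = 10)
  clean <- simulateSerialTransfer(m, spec, 30)
  fit <- fitDilutionFactor(clean, m, spec, cbar0 = 30)
  expect_equal(fit$dilution, 0.43, tolerance = 1e-3)

  noisy <- genSerialTransferTrace(m, spec, 30, noiseSpec(), seed = 41)
  fitN <- fitDilutionFactor(noisy[noisy$series == "transfer", ], m, spec,
                            cbar0 = 30)
  expect_lt(abs(fitN$dilution - 0.43), 0.05)

  # a trace generated at 0.5 is distinguishable from 0.43 at this noise
  spec5 <- serialTransferSpec(dilution = 0.5, nTransfers = 10)
  noisy5 <- genSerialTransferTrace(m, spec5, 30, noiseSpec(), seed = 42)
  fit5 <- fitDilutionFactor(noisy5[noisy5$series == "transfer", ], m, spec5,
                            cbar0 = 30)
  expect_lt(abs(fit5$dilution - 0.5), 0.05)
  expect_lt(abs(fit5$dilution - 0.5), abs(fit5$dilution - 0.43))
})

test_that("sigmoid fitting recovers logistic parameters and flags flat data", {
  t <- seq(0, 20, by = 0.5)
  yTrue <- 1 + 3 / (1 + exp(-(t - 8) / 1.5))
  fit <- fitSigmoid(data.frame(t, yTrue))
  expect_false(fit$flat)
  expect_equal(fit$midpoint, 8, tolerance = 1e-3)
  expect_equal(fit$slope, 1 / 1.5, tolerance = 1e-3)
  # amplitude: plateau (4) relative to the first-frame value (~1)
  expect_equal(fit$amplitude, (4 - yTrue[1]) / yTrue[1], tolerance = 1e-3)

  set.seed(51)
  yN <- yTrue * (1 + rnorm(length(t), 0, 0.05))
  fitN <- fitSigmoid(data.frame(t, yN))
  expect_equal(fitN$amplitude, fit$amplitude, tolerance = 0.05 * 4)

  flat <- fitSigmoid(data.frame(t, rep(2, length(t))))
  expect_true(flat$flat)
  expect_equal(flat$amplitude, 0)
  expect_error(fitSigmoid(data.frame(t = 1:4, y = 1:4)), "at least 6")
})
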