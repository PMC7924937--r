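# Nearest-neighbor duplex thermodynamics against hand-tabulated sums and an
# independently computed reference implementation.

test_that("perfect-match NN sums at 1 M Na+ match hand-tabulated totals", {
  # ACGTA: steps AC, CG, GT, TA plus two A/T terminal penalties, summed by
  # hand from the published parameter table
  d <- duplexThermo("ACGTA", conditions = oneMolar())
  expect_equal(d@dH, -30.0, tolerance = 1e-12)
  expect_equal(d@dS, -85.1, tolerance = 1e-12)
  expect_equal(deltaG(d), -30.0 + 310.15 * 85.1 / 1000, tolerance = 1e-9)

  # AT: a single NN step plus initiation at both A/T ends
  d2 <- duplexThermo("AT", conditions = oneMolar())
  expect_equal(d2@dH, -7.2 + 2 * 2.3, tolerance = 1e-12)
  expect_equal(d2@dS, -20.4 + 2 * 4.1, tolerance = 1e-12)
})

test_that("information-domain duplexes reproduce reference energies under the replication buffer", {
  # frozen values computed with an independent NN implementation using the
  # same published parameter set and sodium-equivalent correction
  d0 <- duplexThermo("AGTGGGTAATAATGA")
  expect_equal(d0@dH, -105.8, tolerance = 1e-9)
  expect_equal(d0@dS, -294.736747, tolerance = 1e-6)
  expect_equal(deltaG(d0), -14.387398, tolerance = 1e-5)
  expect_equal(meltingTemperature(d0), 50.631669, tolerance = 1e-4)

  d1 <- duplexThermo("AAAAGAAGAGAAAGA")
  expect_equal(deltaG(d1), -13.836648, tolerance = 1e-5)
  expect_equal(meltingTemperature(d1), 48.766158, tolerance = 1e-4)
})

test_that("mismatched duplexes match the independent reference", {
  top <- "AGTGGGTAATAATGA"
  perfect <- chartr("ACGT", "TGCA", top)   # bottom, 3'->5' aligned
  swap <- function(bottom, i, b) {
    v <- strsplit(bottom, "")[[1]]; v[i] <- b; paste(v, collapse = "")
  }
  # internal mismatch
  expect_equal(deltaG(duplexThermo(top, swap(perfect, 8, "A"))),
               -11.380793, tolerance = 1e-5)
  # terminal mismatches at either end
  expect_equal(deltaG(duplexThermo(top, swap(perfect, 1, "G"))),
               -14.293223, tolerance = 1e-5)
  expect_equal(deltaG(duplexThermo(top, swap(perfect, 15, "C"))),
               -13.792658, tolerance = 1e-5)
  # tandem mismatch: the unparameterized step contributes no stacking
  dd <- duplexThermo(top, swap(swap(perfect, 7, "C"), 8, "A"))
  expect_equal(deltaG(dd), -9.614243, tolerance = 1e-5)
  expect_gte(dd@nUnparameterized, 1L)
})

test_that("any single internal mismatch weakens or preserves binding", {
  top <- "AGTGGGTAATAATGA"
  perfect <- strsplit(chartr("ACGT", "TGCA", top), "")[[1]]
  ref <- deltaG(duplexThermo(top))
  for (i in seq_along(perfect)) {
    for (b in setdiff(c("A", "C", "G", "T"), perfect[i])) {
      mut <- perfect; mut[i] <- b
      expect_gte(deltaG(duplexThermo(top, paste(mut, collapse = ""))),
                 ref - 1e-9)
    }
  }
})

test_that("melting temperature follows the two-state closed form", {
  # hand evaluation: Tm = 1000*(-100)/(-280 + R ln(1e-7)) - 273.15
  d <- new("DuplexThermo", dH = -100, dS = -280,
           conditions = ionicConditions(totalStrandConc = 4e-7),
           top = "", bottom = "", nUnparameterized = 0L)
  expect_equal(meltingTemperature(d), 47.3355, tolerance = 1e-3)

  # doubling the strand concentration raises Tm (dH < 0)
  d2 <- d; d2@conditions@totalStrandConc <- 8e-7
  expect_gt(meltingTemperature(d2), meltingTemperature(d))

  # unphysical parameters are rejected
  bad <- d; bad@dS <- 100
  expect_error(meltingTemperature(bad), "unphysical")
})

test_that("unbound fraction and Tm are mutually consistent and monotone", {
  d <- duplexThermo("AGTGGGTAATAATGA")
  tm <- meltingTemperature(d)
  expect_equal(unboundFraction(d, tm), 0.5, tolerance = 1e-6)
  grid <- seq(0, 95, by = 0.5)
  u <- unboundFraction(d, grid)
  expect_true(all(diff(u) >= -1e-12))
  expect_true(all(u >= 0 & u <= 1))
  expect_gt(unboundFraction(d, tm + 40), 0.99)
  # a ~10 C Tm shift moves the duplex from mostly bound at the base
  # temperature to mostly unbound 10 C higher
  expect_lt(unboundFraction(d, 45), 0.25)
  weak <- new("DuplexThermo", dH = d@dH,
              dS = 1000 * d@dH / (tm - 10 + 273.15) -
                1.987 * log(d@conditions@totalStrandConc / 4),
              conditions = d@conditions, top = "", bottom = "",
              nUnparameterized = 0L)
  expect_equal(meltingTemperature(weak), tm - 10, tolerance = 1e-6)
  expect_gt(unboundFraction(weak, 55), 0.5)
})

test_that("deltaG is linear in temperature for fixed (dH, dS)", {
  d <- duplexThermo("AGTGGGTAATAATGA")
  g20 <- deltaG(d, 20); g40 <- deltaG(d, 40); g60 <- deltaG(d, 60)
  expect_equal(g40, (g20 + g60) / 2, tolerance = 1e-12)
})

test_that("duplexThermo rejects malformed input", {
  expect_error(duplexThermo("ACGT", "ACG"), "equal length")
  expect_error(duplexThermo("A"), "at least 2")
  expect_error(duplexThermo("ACXT"), "non-ACGT")
  expect_error(duplexThermo("ACGT", "TGXA"), "non-ACGT")
})

test_that("melting-curve fitting recovers the transition from synthetic data", {
  d <- duplexThermo("AGTGGGTAATAATGA")
  tmTrue <- meltingTemperature(d)

  # noiseless curve with flat baselines: Tm recovered within 0.1 C
  clean <- genMeltingCurve(d@dH, d@dS)
  f <- fitMeltingCurve(clean)
  expect_equal(f$tm, tmTrue, tolerance = 0.1)

  # sloped baselines and 2% noise: Tm within 0.5 C
  noisy <- genMeltingCurve(d@dH, d@dS,
                           baselines = list(lower = c(0.1, 0.002),
                                            upper = c(0.85, 0.003)),
                           noise = noiseSpec(0.02, 0), seed = 11)
  fn <- fitMeltingCurve(noisy)
  expect_equal(fn$tm, tmTrue, tolerance = 0.5)
  expect_lt(fn$thermo@dH, 0)

  # degenerate inputs are flagged, not fitted
  tc <- seq(20, 80, by = 2)
  expect_error(fitMeltingCurve(data.frame(tc, rep(1, length(tc)))),
               "no transition")
  expect_error(fitMeltingCurve(data.frame(tc, 0.2 + 0.01 * tc)),
               "no transition")
  expect_error(fitMeltingCurve(clean[1:10, ]), "at least 15")
})

test_that("melting curve object enforces its invariants", {
  d <- duplexThermo("AGTGGGTAATAATGA")
  mc <- meltingCurve(d, seq(20, 90, by = 0.1))
  expect_equal(mc@tm, meltingTemperature(d), tolerance = 1e-9)
  expect_gt(mc@width, 0)
  iTm <- which.min(abs(mc@temperatures - mc@tm))
  expect_equal(mc@unboundFraction[iTm], 0.5, tolerance = 0.02)
})
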