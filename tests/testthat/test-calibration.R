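test_that("a noiseless dilution series is recovered exactly", {
  copies <- rep(10^(5:1), each = 3)
  cq <- -3.3219 * log10(copies) + 40
  cv <- fitStandardCurve(copies, cq)
  expect_equal(cv@slope, -3.3219, tolerance = 1e-9)
  expect_equal(cv@intercept, 40, tolerance = 1e-9)
  expect_equal(cv@rSquared, 1, tolerance = 1e-12)
  expect_equal(cv@nPoints, 15L)
})

test_that("noisy fits match an independent least-squares oracle", {
  set.seed(101)
  for (rep in 1:5) {
    copies <- rep(10^(5:1), each = 3)
    cq <- -3.45 * log10(copies) + 38.5 + rnorm(15, 0, 0.3)
    cv <- fitStandardCurve(copies, cq)
    ## closed-form OLS on the same points
    x <- log10(copies)
    bx <- sum((x - mean(x)) * (cq - mean(cq))) / sum((x - mean(x))^2)
    ax <- mean(cq) - bx * mean(x)
    expect_equal(cv@slope, bx, tolerance = 1e-9)
    expect_equal(cv@intercept, ax, tolerance = 1e-9)
    pred <- ax + bx * x
    r2 <- 1 - sum((cq - pred)^2) / sum((cq - mean(cq))^2)
    expect_equal(cv@rSquared, r2, tolerance = 1e-9)
  }
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fitStandardCurve(rep(100, 3), c(30, 30.1, 29.9)),
               "distinct concentration levels")
  expect_error(fitStandardCurve(c(10, 100), c(NA_real_, NA_real_)),
               "undetermined")
  expect_error(fitStandardCurve(c(-1, 10), c(30, 25)), "positive")
  ## undetermined points are excluded, the rest still fits
  cv <- fitStandardCurve(c(10, 100, 1000), c(36.68, NA, 30.04))
  expect_equal(cv@nPoints, 2L)
})

test_that("cqToCopies inverts the calibration line", {
  cv <- fitStandardCurve(rep(10^(5:1), each = 3),
                         -3.3219 * log10(rep(10^(5:1), each = 3)) + 40)
  expect_equal(cqToCopies(cv, 40), 1, tolerance = 1e-9)
  expect_equal(cqToCopies(cv, 40 - 3.3219), 10, tolerance = 1e-9)
  ## one decade per 3.3219 cycles
  expect_equal(cqToCopies(cv, 36.6781), 10, tolerance = 1e-3)
  ## undetermined propagates as the missing marker
  expect_true(is.na(cqToCopies(cv, NA_real_)))

  ## round trip to 1e-9 relative, and strict monotone decrease
  set.seed(7)
  copies <- 10^runif(50, 0, 6)
  expect_equal(cqToCopies(cv, copiesToCq(cv, copies)) / copies,
               rep(1, 50), tolerance = 1e-9)
  cqs <- sort(runif(20, 15, 45))
  expect_true(all(diff(cqToCopies(cv, cqs)) < 0))
})

test_that("amplification efficiency follows the slope", {
  expect_equal(amplificationEfficiency(-3.3219), 1, tolerance = 1e-4)
  expect_equal(amplificationEfficiency(-3.6), 10^(1 / 3.6) - 1,
               tolerance = 1e-12)
  expect_equal(amplificationEfficiency(-3.6), 0.896, tolerance = 1e-3)
  expect_error(amplificationEfficiency(0), "negative slope")
  expect_error(amplificationEfficiency(2.5), "negative slope")
})

test_that("fitCurves covers every (setting, gene) and NTC validation warns", {
  pe <- simulatePlate(simulationConfig(seed = 9, nPseudoSettings = 3))
  curves <- fitCurves(pe)
  expect_equal(names(curves), settingIds(pe))
  for (s in settingIds(pe)) {
    expect_setequal(names(curves[[s]]), c("transgene", "reference"))
    expect_lt(curves[[s]]$transgene@slope, 0)
    expect_gt(curves[[s]]$transgene@rSquared, 0.99)
  }
  expect_silent(validateNtc(pe))

  ## contaminate one NTC and expect a named warning
  cq <- cqValues(pe)
  info <- wellInfo(pe)
  ntcWell <- info$position[info$task == "ntc"][1]
  cq[ntcWell, 1] <- 28
  assay(pe, "cq") <- cq
  expect_warning(validateNtc(pe), ntcWell)

  tab <- curveTable(curves)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$efficiency_percent > 80 & tab$efficiency_percent < 120))
})
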