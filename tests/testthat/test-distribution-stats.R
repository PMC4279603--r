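test_that("population statistics use the divisor-n convention", {
  st <- populationStats(c(1, 3), nominal = 2.5)
  expect_equal(st$mean, 2)
  expect_equal(st$sdPopulation, 1)          # divisor n, never 1.414...
  expect_false(isTRUE(all.equal(st$sdPopulation, sd(c(1, 3)))))
  expect_equal(st$rsd, 50)
  expect_equal(st$relAbsDeviation, 20)

  same <- populationStats(rep(0.1, 50), nominal = 0.1)
  expect_equal(same$rsd, 0)
  expect_equal(same$relAbsDeviation, 0)

  ## n * variance equals the exact sum of squared deviations
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(37, 10, 2)
    st <- populationStats(x, nominal = 10)
    expect_equal(st$sdPopulation^2 * length(x), sum((x - mean(x))^2),
                 tolerance = 1e-12)
  }
  expect_error(populationStats(numeric(0), 1), "non-empty")
  expect_error(populationStats(c(-1, 1), 1), "RSD undefined")
  expect_error(populationStats(c(1, 2), nominal = 0), "positive")
})

test_that("empirical skewness matches hand values and is affine-equivariant", {
  expect_equal(empiricalSkewness(c(-1, 0, 1)), 0)
  expect_equal(empiricalSkewness(c(0, 0, 0, 1)), 1.1547, tolerance = 1e-4)
  ## brute-force formula evaluation as the oracle
  x <- c(0, 0, 0, 1)
  m <- mean(x); s <- sqrt(sum((x - m)^2) / length(x))
  expect_equal(empiricalSkewness(x), sum(((x - m) / s)^3) / length(x),
               tolerance = 1e-12)

  set.seed(88)
  for (i in 1:10) {
    x <- rexp(100)
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 4)
    expect_equal(empiricalSkewness(a + b * x), empiricalSkewness(x),
                 tolerance = 1e-10)
    expect_equal(empiricalSkewness(a - b * x), -empiricalSkewness(x),
                 tolerance = 1e-10)
  }
  expect_error(empiricalSkewness(rep(2, 5)), "undefined")
  expect_error(empiricalSkewness(1), "at least 2")
})

test_that("binning is equal-width, conservative and edge-correct", {
  d <- binValues(0:9, nClasses = 5)
  expect_equal(classCounts(d), rep(2L, 5))
  expect_equal(classEdges(d), seq(0, 9, length.out = 6))

  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(500, 0.1, 0.02)
    d <- binValues(x, nClasses = 17)
    expect_equal(sum(classCounts(d)), 500)              # conservation
    expect_equal(max(diff(range(diff(classEdges(d))))), 0, tolerance = 1e-12)
    ## min sits in the first class, max in the last
    expect_gt(classCounts(d)[1], 0)
    expect_gt(classCounts(d)[17], 0)
  }

  ## interval convention: (lower, upper], first class closed on the left
  d <- binValues(c(0, 1, 1, 2), nClasses = 2)
  expect_equal(classCounts(d), c(3L, 1L))

  expect_warning(d0 <- binValues(rep(0.1, 100), nClasses = 20), "identical")
  expect_equal(sum(classCounts(d0) > 0), 1)
  expect_equal(sum(classCounts(d0)), 100)
  expect_error(binValues(1:5, nClasses = 1), "at least 2")
})

test_that("the simplified chi-square test uses open-tail Gaussian masses", {
  ## internal edges at the Gaussian quintiles: every class expects n/5, so
  ## equal observed counts give chi-square 0 and p = 100%
  edges <- c(-3, qnorm(c(0.2, 0.4, 0.6, 0.8)), 3)
  d <- new("FrequencyDistribution", edges = edges,
           counts = rep(20L, 5), nTotal = 100L)
  res <- chiSquareNormality(d, mean = 0, sd = 1)
  expect_equal(res$chiSquare, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
  expect_equal(res$df, 2L)                    # nClasses - 3 by default
  expect_equal(chiSquareNormality(d, 0, 1, df = 4)$df, 4L)

  ## hand-computed sum of d^2/m for unequal counts (no marginal merging)
  d2 <- new("FrequencyDistribution", edges = edges,
            counts = c(10L, 20L, 40L, 20L, 10L), nTotal = 100L)
  res2 <- chiSquareNormality(d2, mean = 0, sd = 1)
  expect_equal(res2$chiSquare,
               (10 - 20)^2 / 20 + 0 + (40 - 20)^2 / 20 + 0 + (10 - 20)^2 / 20,
               tolerance = 1e-9)
  expect_equal(res2$p, pchisq(res2$chiSquare, 2, lower.tail = FALSE))

  ## brute-force oracle on randomly binned Gaussian-ish data
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(400, 5, 2)
    d <- binValues(x, nClasses = 12)
    m0 <- mean(x); s0 <- popSd(x)
    res <- chiSquareNormality(d, m0, s0)
    e <- classEdges(d); e[1] <- -Inf; e[length(e)] <- Inf
    expected <- (pnorm(e[-1], m0, s0) - pnorm(e[-length(e)], m0, s0)) * 400
    chiRef <- sum((classCounts(d) - expected)^2 / expected)
    expect_equal(res$chiSquare, chiRef, tolerance = 1e-10)
  }

  ## distribution far from the Gaussian: zero expected mass must error
  far <- new("FrequencyDistribution", edges = 0:5, counts = rep(10L, 5),
             nTotal = 50L)
  expect_error(chiSquareNormality(far, mean = 1000, sd = 0.1),
               "fewer classes")
  expect_error(chiSquareNormality(far, mean = 1, sd = 0), "positive")
  tiny <- new("FrequencyDistribution", edges = 0:3, counts = rep(5L, 3),
              nTotal = 15L)
  expect_error(chiSquareNormality(tiny, 1, 1), "at least 4")
})

test_that("scale invariance: chi-square is unchanged by affine rescaling", {
  set.seed(77)
  x <- rnorm(300, 0.1, 0.01)
  d1 <- binValues(x, 10)
  r1 <- chiSquareNormality(d1, mean(x), popSd(x))
  y <- 3 + 40 * x
  d2 <- binValues(y, 10)
  r2 <- chiSquareNormality(d2, mean(y), popSd(y))
  expect_equal(r1$chiSquare, r2$chiSquare, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("the coverage cut-off picks the largest qualifying count threshold", {
  d <- new("FrequencyDistribution", edges = seq(0, 0.4, 0.1),
           counts = c(50L, 4800L, 100L, 50L), nTotal = 5000L)
  co <- cutoffSummary(d)
  expect_equal(co@countThreshold, 4800L)
  expect_equal(co@includedClasses, 2L)
  expect_equal(co@achievedCoverage, 0.96)
  expect_equal(co@middleClass, 0.2)           # single included class
  expect_equal(co@halfRange, 0)

  ## middle class and half range from the included upper limits
  d2 <- new("FrequencyDistribution", edges = seq(0, 0.5, 0.1),
            counts = c(30L, 400L, 450L, 100L, 20L), nTotal = 1000L)
  co2 <- cutoffSummary(d2)
  expect_equal(co2@countThreshold, 100L)
  expect_equal(co2@includedClasses, 2:4)
  expect_equal(co2@middleClass, (0.4 + 0.2) / 2)
  expect_equal(co2@halfRange, (0.4 - 0.2) / 2)
  expect_gte(co2@achievedCoverage, 0.95)

  ## randomized populations: the invariants of the construction
  set.seed(9)
  for (i in 1:25) {
    x <- rnorm(2000, 0.1, runif(1, 0.005, 0.05))
    d <- binValues(x, sample(10:30, 1))
    co <- cutoffSummary(d)
    counts <- classCounts(d)
    expect_gte(sum(counts[co@includedClasses]), 0.95 * 2000)
    ## a strictly larger threshold would fall below the target
    bigger <- counts[counts >= co@countThreshold + 1L]
    expect_lt(sum(bigger), 0.95 * 2000)
    expect_equal(co@middleClass,
                 (co@lastUpper + co@firstUpper) / 2, tolerance = 1e-12)
    expect_equal(co@halfRange,
                 (co@lastUpper - co@firstUpper) / 2, tolerance = 1e-12)
  }
})
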