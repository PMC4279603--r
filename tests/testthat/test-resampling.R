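test_that("plans are deterministic, well-formed and substream-stable", {
  p1 <- buildPlan(16, ks = c(2, 5, 16), nCombinations = 200, seed = 99)
  p2 <- buildPlan(16, ks = c(2, 5, 16), nCombinations = 200, seed = 99)
  expect_equal(p1, p2)
  expect_false(isTRUE(all.equal(
    p1, buildPlan(16, ks = c(2, 5, 16), nCombinations = 200, seed = 100))))

  ## each k has its own substream: a single-k plan reproduces the k-slice
  ## of the full plan, so partial re-runs are possible
  p5 <- buildPlan(16, ks = 5, nCombinations = 200, seed = 99)
  expect_equal(p5@combos[["5"]], p1@combos[["5"]])

  ## indices are distinct within each (gene, isolation) draw
  for (p in names(p1@combos[["5"]]))
    expect_true(all(apply(p1@combos[["5"]][[p]], 1, anyDuplicated) == 0))

  ## at k = pool size only one subset exists
  expect_true(all(p1@combos[["16"]][["transgene.1"]] ==
                  rep(1:16, each = 200)))

  expect_error(buildPlan(16, ks = 17, nCombinations = 10, seed = 1),
               "transgene.1")
  expect_error(
    buildPlan(c(transgene.1 = 16, transgene.2 = 16,
                reference.1 = 3, reference.2 = 16),
              ks = 4, nCombinations = 10, seed = 1),
    "reference.2|reference.1")
})

test_that("constant copies collapse every population to a single value", {
  pe <- constantExperiment(tgCopies = 20, refCopies = 20000, n = 3)
  plan <- buildPlan(3, ks = 2:3, nCombinations = 500, seed = 4)
  pops <- evaluatePlan(plan, pe)
  expect_equal(names(pops), c("s1|2", "s1|3"))
  for (pop in pops) {
    expect_length(populationValues(pop), 500)
    expect_equal(populationValues(pop), rep(0.1, 500), tolerance = 1e-9)
    expect_equal(popSd(populationValues(pop)), 0, tolerance = 1e-12)
  }
})

test_that("sampled populations agree with exhaustive enumeration on tiny pools", {
  set.seed(21)
  pools <- list(
    transgene.1 = c(18, 22, 25), transgene.2 = c(15, 20, 24),
    reference.1 = c(19500, 20500, 21000), reference.2 = c(18800, 20000, 21700))
  exact <- enumeratePopulation(pools, k = 2)
  expect_length(exact, 81)
  exactMean <- mean(exact)
  exactSd <- popSd(exact)
  m4 <- popMoment(exact, 4)

  pe <- exactExperiment(list(s1 = pools))
  plan <- buildPlan(3, ks = 2, nCombinations = 5000, seed = 31)
  vals <- populationValues(evaluatePlan(plan, pe)[["s1|2"]])
  expect_length(vals, 5000)

  seMean <- exactSd / sqrt(5000)
  seSd <- sqrt((m4 - exactSd^4) / (4 * exactSd^2 * 5000))
  expect_lt(abs(mean(vals) - exactMean), 3 * seMean)
  expect_lt(abs(popSd(vals) - exactSd), 3 * seSd)
})

test_that("the same index tuples are applied to every setting", {
  ## setting s2 doubles every transgene copy number; with shared tuples the
  ## i-th GMO value must double exactly, combination by combination
  pools1 <- list(
    transgene.1 = c(18, 22, 25), transgene.2 = c(15, 20, 24),
    reference.1 = c(19500, 20500, 21000), reference.2 = c(18800, 20000, 21700))
  pools2 <- pools1
  pools2$transgene.1 <- 2 * pools2$transgene.1
  pools2$transgene.2 <- 2 * pools2$transgene.2
  pe <- exactExperiment(list(s1 = pools1, s2 = pools2))
  plan <- buildPlan(3, ks = c(2, 3), nCombinations = 1000, seed = 8)
  pops <- evaluatePlan(plan, pe)
  for (k in c(2, 3))
    expect_equal(populationValues(pops[[paste0("s2|", k)]]),
                 2 * populationValues(pops[[paste0("s1|", k)]]),
                 tolerance = 1e-9)
})

test_that("plan export/import round-trips bit-identically", {
  plan <- buildPlan(16, ks = c(2, 3), nCombinations = 50, seed = 123)
  f <- withr::local_tempfile(fileext = ".tsv")
  exportPlan(plan, f)
  plan2 <- importPlan(f)
  expect_equal(plan2, plan)
})

test_that("undetermined wells shrink pools consistently under 'exclude'", {
  pools <- list(
    transgene.1 = c(18, 22, NA), transgene.2 = c(15, 20, 24),
    reference.1 = c(19500, 20500, 21000), reference.2 = c(18800, 20000, 21700))
  pe <- exactExperiment(list(s1 = pools))

  expect_warning(shrunk <- samplePools(pe, conversionConfig()),
                 "undetermined")
  expect_equal(unname(lengths(shrunk)), c(2L, 3L, 3L, 3L))

  ## a plan built for the unshrunken pools no longer fits
  plan16 <- buildPlan(3, ks = 2, nCombinations = 20, seed = 1)
  expect_error(suppressWarnings(evaluatePlan(plan16, pe)),
               "do not match")

  ## one built on the shrunken sizes evaluates fine
  planOk <- buildPlan(lengths(shrunk), ks = 2, nCombinations = 20, seed = 1)
  pops <- suppressWarnings(evaluatePlan(planOk, pe))
  expect_length(populationValues(pops[["s1|2"]]), 20)

  ## zero_copies keeps the full pools
  cfg0 <- conversionConfig(missingCqPolicy = "zero_copies")
  expect_equal(unname(lengths(samplePools(pe, cfg0))), rep(3L, 4))

  ## pools below max(ks) are refused
  poolsBad <- pools
  poolsBad$transgene.1 <- c(18, NA, NA)
  peBad <- exactExperiment(list(s1 = poolsBad))
  expect_error(suppressWarnings(
    evaluatePlan(buildPlan(3, ks = 2, nCombinations = 10, seed = 1), peBad)),
    "smaller than max")
})
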