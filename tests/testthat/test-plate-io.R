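test_that("a full-plate export parses into the expected record set", {
  pe <- simulatePlate(simulationConfig(seed = 11, nPseudoSettings = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSettingTable(pe, "setting1", f)

  layout <- defaultPlateLayout(nominalGmoPercent = 0.1)
  rec <- readPlateTable(f, layout)
  expect_equal(nrow(rec), 96)
  expect_equal(sum(rec$task == "standard"), 30)   # 2 x 5 levels x 3
  expect_equal(sum(rec$task == "ntc"), 2)
  expect_equal(sum(rec$task == "sample"), 64)     # 2 x (16 + 16)
  for (g in c("transgene", "reference"))
    expect_equal(as.integer(table(rec$isolation[rec$task == "sample" &
                                                rec$gene == g])),
                 c(16L, 16L))
  ## NTC Cq arrives as the explicit missing marker, not zero
  expect_true(all(is.na(rec$cq[rec$task == "ntc"])))
  ## known copies only on standards
  expect_true(all(!is.na(rec$knownCopies[rec$task == "standard"])))
  expect_true(all(is.na(rec$knownCopies[rec$task != "standard"])))
})

test_that("malformed exports fail loudly", {
  layout <- defaultPlateLayout(nominalGmoPercent = 0.1)
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("Well,Target,Task,Cq,Quantity", empty)
  expect_error(readPlateTable(empty), "no rows")

  pe <- simulatePlate(simulationConfig(seed = 11, nPseudoSettings = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSettingTable(pe, "setting1", f)

  dup <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(f)
  writeLines(c(lines, lines[2]), dup)
  expect_error(readPlateTable(dup), "duplicate")

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[-2], short)  # drop well A1
  expect_error(readPlateTable(short, layout), "A1")

  bad <- withr::local_tempfile(fileext = ".csv")
  lines[3] <- sub(",[0-9.]+,", ",not-a-number,", lines[3])
  writeLines(lines, bad)
  expect_error(readPlateTable(bad), "unparseable Cq")
})

test_that("write/read round trip preserves records and row order is irrelevant", {
  pe <- simulatePlate(simulationConfig(seed = 3, nPseudoSettings = 1))
  layout <- plateLayout(pe)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSettingTable(pe, "setting1", f)
  rec <- readPlateTable(f, layout)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writePlateTable(rec, f2)
  expect_equal(readPlateTable(f2, layout), rec, tolerance = 1e-12)

  ## shuffled input rows give the same experiment
  lines <- readLines(f)
  set.seed(1)
  shuffled <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1], sample(lines[-1])), shuffled)
  expect_equal(readPlateTable(shuffled, layout), rec, tolerance = 1e-12)

  ## tab-separated dialect is autodetected
  f3 <- withr::local_tempfile(fileext = ".txt")
  writePlateTable(rec, f3, sep = "\t")
  expect_equal(readPlateTable(f3, layout), rec, tolerance = 1e-12)
})

test_that("assembleExperiment stacks settings and enforces consistency", {
  pe <- simulatePlate(simulationConfig(seed = 5, nPseudoSettings = 5))
  layout <- plateLayout(pe)
  tabs <- lapply(settingIds(pe), function(s) {
    f <- tempfile(fileext = ".csv")
    writeSettingTable(pe, s, f)
    readPlateTable(f, layout)
  })
  names(tabs) <- settingIds(pe)

  pe2 <- assembleExperiment(layout, tabs)
  expect_s4_class(pe2, "PlateExperiment")
  expect_equal(ncol(pe2), 5)
  expect_equal(cqValues(pe2), cqValues(pe), tolerance = 1e-12)

  expect_s4_class(assembleExperiment(layout, tabs[1]), "PlateExperiment")
  expect_error(assembleExperiment(layout, list()), "at least one")

  crippled <- tabs
  crippled[[2]] <- crippled[[2]][crippled[[2]]$position != "D12", ]
  expect_error(assembleExperiment(layout, crippled), "D12")
})

test_that("layout YAML round-trips and the shipped example parses", {
  layout <- defaultPlateLayout(nominalGmoPercent = 0.1, conversionFactor = 0.5)
  f <- withr::local_tempfile(fileext = ".yaml")
  writePlateLayout(layout, f)
  layout2 <- readPlateLayout(f)
  expect_equal(layout2@standards, layout@standards)
  expect_equal(layout2@samples, layout@samples)
  expect_equal(nominalGmoPercent(layout2), 0.1)
  expect_equal(conversionFactor(layout2), 0.5)

  ex <- system.file("extdata", "example_layout.yaml", package = "qpcrPlateVar")
  exTab <- system.file("extdata", "example_plate_setting1.csv",
                       package = "qpcrPlateVar")
  lay <- readPlateLayout(ex)
  expect_s4_class(lay, "PlateLayout")
  rec <- readPlateTable(exTab, lay)
  expect_equal(nrow(rec), 96)
})

test_that("layout validity catches inconsistent plates", {
  expect_error(PlateLayout(
    standards = data.frame(gene = "transgene", position = "A1", copies = 10),
    ntc = data.frame(gene = character(), position = character()),
    samples = data.frame(gene = rep(c("transgene", "reference"), each = 2),
                         position = c("A2", "A3", "B1", "B2"),
                         isolation = c(1L, 2L, 1L, 1L)),
    nominalGmoPercent = 0.1), "isolation")
  expect_error(PlateLayout(
    standards = data.frame(gene = "transgene", position = c("A1", "A1"),
                           copies = c(10, 100)),
    ntc = data.frame(gene = character(), position = character()),
    samples = data.frame(gene = rep(c("transgene", "reference"), each = 2),
                         position = c("A2", "A3", "B1", "B2"),
                         isolation = c(1L, 2L, 1L, 2L)),
    nominalGmoPercent = 0.1), "duplicated")
})
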