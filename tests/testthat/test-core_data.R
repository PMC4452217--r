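test_that("CSV reader reconstructs a small survey with records and mask", {
  traps_csv <- tempfile(fileext = ".csv")
  pellets_csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "location_id,habitat,line_id,night,traps_set,possum_captures,nontarget_captures,sprung_empty",
    "L1,forest,AA,1,10,1,0,0", "L1,forest,AA,2,10,0,1,0",
    "L1,forest,DD,1,10,0,0,0", "L1,forest,DD,2,10,0,0,2",
    "L1,forest,MM,1,10,0,0,0", "L1,forest,MM,2,10,0,0,0",
    "L2,nonforest,AA,1,10,0,0,0", "L2,nonforest,DD,1,10,0,0,0"),
    traps_csv)
  writeLines(c(
    "location_id,habitat,transect_id,transect_presence",
    "L1,forest,A,1", "L1,forest,D,0", "L1,forest,M,0", "L1,forest,P,0",
    "L2,nonforest,A,0", "L2,nonforest,D,0"),
    pellets_csv)
  ds <- readSurveyCsv(traps_csv, pellets_csv)
  expect_s4_class(ds, "SurveyDataset")
  expect_equal(nLocations(ds), 2L)
  expect_equal(nrow(trapRecords(ds)), 8L)
  expect_equal(nrow(pelletRecords(ds)), 6L)
  expect_equal(unname(habitats(ds)), c("forest", "nonforest"))

  mask <- surveyedMask(ds)
  expect_false(mask["L1", "PP"])   # no PP rows for L1
  expect_false(mask["L2", "MM"])
  expect_false(mask["L2", "M"])
  expect_true(all(mask["L1", c("AA", "DD", "MM", "A", "D", "M", "P")]))
})

test_that("reader rejects malformed rows with row-level diagnostics", {
  traps_csv <- tempfile(fileext = ".csv")
  pellets_csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "location_id,habitat,line_id,night,traps_set,possum_captures,nontarget_captures,sprung_empty",
    "L1,forest,AA,1,10,11,0,0"), traps_csv)
  writeLines("location_id,habitat,transect_id,transect_presence", pellets_csv)
  expect_error(readSurveyCsv(traps_csv, pellets_csv), "row\\(s\\) 1")

  writeLines(c(
    "location_id,habitat,line_id,night,traps_set,possum_captures,nontarget_captures,sprung_empty",
    "L1,forest,AA,3,10,0,0,0"), traps_csv)
  expect_error(readSurveyCsv(traps_csv, pellets_csv), "night")

  writeLines(c("location_id,habitat,line_id",
               "L1,forest,AA"), traps_csv)
  expect_error(readSurveyCsv(traps_csv, pellets_csv), "missing column")
})

test_that("constructor enforces record invariants", {
  ids <- "L1"
  tr <- fullTrapGrid(ids)
  tr$possum_captures[1] <- 5L; tr$nontarget_captures[1] <- 4L
  tr$sprung_empty[1] <- 3L  # 12 > 10 traps
  expect_error(SurveyDataset(makeLocations(ids), tr, fullPelletGrid(ids)),
               "exceed traps_set")

  tr <- rbind(fullTrapGrid(ids), fullTrapGrid(ids)[1, ])
  expect_error(SurveyDataset(makeLocations(ids), tr, fullPelletGrid(ids)),
               "duplicate")

  pe <- fullPelletGrid(c("L1", "LX"))  # LX not declared
  expect_error(SurveyDataset(makeLocations(ids), fullTrapGrid(ids), pe),
               "not listed")
})

test_that("plot-level pellet input collapses to the transect presence bit", {
  ids <- "L1"
  pe <- fullPelletGrid(ids)[, c("location_id", "transect_id")]
  plots <- matrix(0L, 4, 30, dimnames = list(NULL, sprintf("plot_%02d", 1:30)))
  plots[2, 17] <- 1L  # a single positive plot on transect D
  pe <- cbind(pe, plots)
  ds <- SurveyDataset(makeLocations(ids), fullTrapGrid(ids), pe)
  rec <- pelletRecords(ds)
  expect_equal(rec$presence[rec$transect_id == "D"], 1L)
  expect_equal(sum(rec$presence), 1L)
})

test_that("write/read round trip is the identity on simulated datasets", {
  for (seed in c(2L, 31L)) {
    sim <- simulateSurvey(simDesign(nForest = 12L, nNonforest = 9L,
                                    seed = seed))
    traps_csv <- tempfile(fileext = ".csv")
    pellets_csv <- tempfile(fileext = ".csv")
    writeSurveyCsv(sim$dataset, traps_csv, pellets_csv)
    back <- readSurveyCsv(traps_csv, pellets_csv)
    expect_equal(back@locations, sim$dataset@locations)
    expect_equal(back@traps, sim$dataset@traps)
    expect_equal(back@pellets, sim$dataset@pellets)
    expect_equal(surveyedMask(back), surveyedMask(sim$dataset))
  }
})

test_that("an empty dataset writes header-only files that read back empty", {
  ds <- SurveyDataset(makeLocations(character(0)))
  traps_csv <- tempfile(fileext = ".csv")
  pellets_csv <- tempfile(fileext = ".csv")
  writeSurveyCsv(ds, traps_csv, pellets_csv)
  expect_length(readLines(traps_csv), 1L)
  back <- readSurveyCsv(traps_csv, pellets_csv)
  expect_equal(nLocations(back), 0L)
  expect_equal(nrow(trapRecords(back)), 0L)
})

test_that("detection summary follows the line/night indexing rules", {
  ids <- "L1"
  tr <- fullTrapGrid(ids)
  # AA: night-1 capture only; DD: night-2 captures only
  tr$possum_captures[tr$line_id == "AA" & tr$night == 1] <- 1L
  tr$possum_captures[tr$line_id == "DD" & tr$night == 2] <- 2L
  pe <- fullPelletGrid(ids)
  pe$presence[pe$transect_id == "M"] <- 1L
  ds <- SurveyDataset(makeLocations(ids), tr, pe)

  both <- summarizeDetections(ds, "both")
  expect_equal(unname(both@X["L1", c("AA", "DD")]), c(1, 1))
  first <- summarizeDetections(ds, "first_only")
  expect_equal(unname(first@X["L1", c("AA", "DD")]), c(1, 0))
  expect_equal(unname(first@Y["L1", "DD"]), 0)
  expect_equal(unname(first@E["L1", "DD"]), 10)
  # pellet columns are night-invariant; any positive plot marks the transect
  expect_equal(both@X[, 5:8], first@X[, 5:8])
  expect_equal(unname(both@X["L1", "M"]), 1)
})

test_that("locations with no surveyed units are dropped with a warning", {
  ids <- c("L1", "L2")
  tr <- fullTrapGrid("L1")
  pe <- fullPelletGrid("L1")
  ds <- SurveyDataset(makeLocations(ids), tr, pe)
  expect_warning(sm <- summarizeDetections(ds), "L2")
  expect_equal(locationIds(sm), "L1")
})

test_that("trap detection equals positive capture and positive TCI", {
  sim <- simulateSurvey(simDesign(nForest = 40L, nNonforest = 40L,
                                  seed = 17L))
  for (ngt in c("both", "first_only")) {
    sm <- summarizeDetections(sim$dataset, ngt)
    obs <- !is.na(sm@C)
    expect_identical((sm@C[obs] > 0), (sm@X[, 1:4][obs] == 1))
    expect_identical((sm@C[obs] > 0), (sm@Y[obs] > 0))
  }
})
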