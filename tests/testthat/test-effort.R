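test_that("subsampling at full effort returns the input dataset", {
  sim <- simulateSurvey(simDesign(nForest = 10L, nNonforest = 10L,
                                  seed = 4L, missingLineFraction = 0))
  reps <- subsampleLines(sim$dataset, effortSpec(4L, "both", 3L, seed = 1L))
  for (r in reps) {
    expect_identical(r@traps, sim$dataset@traps)
    expect_identical(r@pellets, sim$dataset@pellets)
  }
})

test_that("each line is retained with frequency 1/4 when one line is drawn", {
  ds <- SurveyDataset(makeLocations("L1"), fullTrapGrid("L1"),
                      fullPelletGrid("L1"))
  reps <- subsampleLines(ds, effortSpec(1L, "both", 10000L, seed = 99L))
  picked <- vapply(reps, function(r) trapRecords(r)$line_id[1], character(1))
  freq <- table(factor(picked, levels = TRAPLINES)) / length(picked)
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("locations with too few surveyed lines keep them all, with warning", {
  ids <- c("L1", "L2")
  tr <- rbind(fullTrapGrid("L1"),
              fullTrapGrid("L2", lines = c("AA", "DD")))
  ds <- SurveyDataset(makeLocations(ids), tr, fullPelletGrid(ids))
  expect_warning(reps <- subsampleLines(ds, effortSpec(3L, "both", 5L,
                                                       seed = 3L)),
                 "L2")
  for (r in reps) {
    kept <- trapRecords(r)
    expect_setequal(unique(kept$line_id[kept$location_id == "L2"]),
                    c("AA", "DD"))
    expect_equal(length(unique(kept$line_id[kept$location_id == "L1"])), 3L)
  }
})

test_that("pellet transects are never subsampled", {
  sim <- simulateSurvey(simDesign(nForest = 8L, nNonforest = 8L, seed = 10L))
  reps <- subsampleLines(sim$dataset, effortSpec(1L, "both", 4L, seed = 5L))
  for (r in reps)
    expect_identical(r@pellets, sim$dataset@pellets)
})

test_that("subsampling distribution is invariant to line relabelling", {
  ds <- SurveyDataset(makeLocations("L1"), fullTrapGrid("L1"),
                      fullPelletGrid("L1"))
  # permute labels: AA<->PP, DD<->MM
  perm <- c(AA = "PP", DD = "MM", MM = "DD", PP = "AA")
  tr2 <- trapRecords(ds)
  tr2$line_id <- unname(perm[tr2$line_id])
  ds2 <- SurveyDataset(makeLocations("L1"), tr2, fullPelletGrid("L1"))
  freq_of <- function(d, seed) {
    reps <- subsampleLines(d, effortSpec(1L, "both", 4000L, seed = seed))
    picked <- vapply(reps, function(r) trapRecords(r)$line_id[1],
                     character(1))
    table(factor(picked, levels = TRAPLINES)) / length(picked)
  }
  f1 <- freq_of(ds, 11L)
  f2 <- freq_of(ds2, 12L)
  # two-sample binomial comparison at ~0.25: se of difference ~0.0097
  expect_true(all(abs(f1 - f2) < 0.03))
})

test_that("the full-effort grid cell reproduces the baseline exactly and
           bias ranges tighten as lines are added", {
  sim <- simulateSurvey(simDesign(nForest = 25L, nNonforest = 0L,
                                  psi = c(forest = 0.8, nonforest = 0.4),
                                  lambda = c(forest = 4.5, nonforest = 2),
                                  missingLineFraction = 0, seed = 31L))
  cfg <- quickConfig(burnIn = 150L, keptIter = 400L)
  grid <- runEffortGrid(sim$dataset, cfg, nLines = c(1L, 2L, 4L),
                        nights = "both", nReplicates = 6L, seed = 8L)
  full <- grid[["4lines_both"]]
  expect_true(all(full@relativeBias$rel_bias == 0))
  base <- full@baseline
  est <- full@replicateEstimates
  for (r in unique(est$replicate))
    expect_identical(est$mean[est$replicate == r], base$mean)

  width <- vapply(grid, function(g) {
    s <- g@summaries[g@summaries$parameter == "zlambda", ]
    s$max_rel_bias - s$min_rel_bias
  }, numeric(1))
  expect_gt(width[["1lines_both"]], width[["4lines_both"]])
  expect_gte(width[["2lines_both"]], width[["4lines_both"]])
  # replicate bias ranges at reduced effort straddle zero
  rb <- grid[["1lines_both"]]@summaries
  rb <- rb[rb$parameter == "zlambda", ]
  expect_lte(rb$min_rel_bias, 0)
  expect_gte(rb$max_rel_bias, 0)
})

test_that("night comparison reports both regimes, pooled and stratified", {
  sim <- simulateSurvey(simDesign(nForest = 20L, nNonforest = 20L,
                                  seed = 44L))
  cmp <- compareNights(sim$dataset, quickConfig(burnIn = 150L,
                                               keptIter = 500L))
  expect_setequal(unique(cmp$nights), c("both", "first_only"))
  expect_setequal(unique(cmp$strata), c("pooled", "by_habitat"))
  psi <- cmp[cmp$parameter == "psi" & cmp$strata == "pooled", ]
  # occupancy is night-invariant to within posterior spread
  d <- abs(diff(psi$mean))
  expect_lt(d, 2 * max(psi$sd))
})

test_that("night comparison collapses when only night-1 records exist", {
  ids <- c("L1", "L2", "L3", "L4")
  tr <- fullTrapGrid(ids, nights = 1)
  tr$possum_captures[tr$location_id == "L1" & tr$line_id == "AA"] <- 1L
  pe <- fullPelletGrid(ids)
  pe$presence[pe$location_id == "L2" & pe$transect_id == "A"] <- 1L
  ds <- SurveyDataset(makeLocations(ids), tr, pe)
  a <- summarizeDetections(ds, "both")
  b <- summarizeDetections(ds, "first_only")
  expect_identical(a@X, b@X)
  expect_identical(a@Y, b@Y)
  expect_identical(a@E, b@E)
  cfg <- quickConfig(burnIn = 100L, keptIter = 300L)
  expect_identical(posteriorDraws(fitOccAbund(a, cfg)),
                   posteriorDraws(fitOccAbund(b, cfg)))
})
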