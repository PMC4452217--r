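test_that("log-likelihood closed forms hold on single-location states", {
  # 8 observed detections, no TCI terms, z = 1, p = 0.5 everywhere
  X <- matrix(1, 1, 8)
  d <- makeDetSummary(X, C = matrix(c(1, 1, 1, 1), 1, 4))
  ll <- logLikelihood(list(z = 1, p_trap = 0.5, p_pellet = 0.5, lambda = 3),
                      d)
  expect_equal(ll, 8 * log(0.5))

  # unoccupied location with nothing observed anywhere: probability 1
  X0 <- matrix(0, 1, 8)
  d0 <- makeDetSummary(X0, Y = matrix(0, 1, 4), E = matrix(20, 1, 4),
                       C = matrix(0, 1, 4))
  expect_equal(logLikelihood(list(z = 0, p_trap = 0.5, p_pellet = 0.5,
                                  lambda = 3), d0), 0)

  # a detection at an unoccupied location is impossible
  d1 <- makeDetSummary(matrix(c(1, rep(0, 7)), 1, 8),
                       C = matrix(c(1, 0, 0, 0), 1, 4))
  expect_identical(logLikelihood(list(z = 0, p_trap = 0.5, p_pellet = 0.5,
                                      lambda = 3), d1), -Inf)
})

test_that("log-likelihood matches an independent direct evaluation", {
  set.seed(101)
  sim <- simulateSurvey(simDesign(nForest = 6L, nNonforest = 5L, seed = 14L))
  sm <- summarizeDetections(sim$dataset)
  z <- as.numeric(rowSums(sm@X == 1, na.rm = TRUE) > 0)
  z[z == 0] <- rbinom(sum(z == 0), 1, 0.5)
  for (mode in c("count_offset", "tci_rounded")) {
    for (strata in c("pooled", "by_habitat")) {
      cfg <- modelConfig(likelihoodMode = mode, strata = strata)
      lambda <- if (strata == "pooled") 3.1 else c(4.2, 1.7)
      state <- list(z = z, p_trap = 0.45, p_pellet = 0.71, lambda = lambda)
      expect_equal(
        logLikelihood(state, sm, cfg),
        directLogLik(z, 0.45, 0.71, lambda, sm@X, sm@Y, sm@E, sm@C,
                     mode = mode, habitat = sm@habitat,
                     stratified = (strata == "by_habitat")),
        info = paste(mode, strata))
    }
  }
})

test_that("enumeration posterior matches the single-site closed form", {
  # one location, 8 observed non-detections, no TCI data:
  # posterior ~ Beta(1,1) x [psi (1-p)^8 + (1-psi)]
  X <- matrix(0, 1, 8)
  d <- makeDetSummary(X)
  p <- 0.5
  grid <- seq(0, 1, length.out = 301)
  bf <- bruteForcePosterior(d, list(p_trap = p, p_pellet = p, lambda = 2),
                            grid)
  expect_equal(sum(bf$mass), 1)
  ref <- grid * (1 - p)^8 + (1 - grid)
  refMass <- possumOccAb:::trapezoidMass(grid, ref)
  expect_equal(bf$mass, refMass, tolerance = 1e-10)

  # two-location fixture normalises too
  bf2 <- bruteForcePosterior(summarizeDetections(makeTinyDataset()),
                             list(p_trap = 0.4, p_pellet = 0.3, lambda = 1))
  expect_equal(sum(bf2$mass), 1)
  expect_error(bruteForcePosterior(
    makeDetSummary(matrix(0, 13, 8)),
    list(p_trap = 0.5, p_pellet = 0.5, lambda = 1)), "12")
})

test_that("Gelman-Rubin statistic behaves across convergence regimes", {
  # identical chains: R-hat = sqrt((n-1)/n), i.e. 1 up to the finite-n term
  x <- rnorm(500)
  expect_equal(gelmanRhat(cbind(x, x)), 1, tolerance = 0.005)
  expect_identical(gelmanRhat(cbind(rep(2, 100), rep(2, 100))), 1)

  set.seed(33)
  null_chains <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(gelmanRhat(null_chains), 1.05)

  divergent <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelmanRhat(divergent), 3)
  expect_error(gelmanRhat(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("Gelman-Rubin statistic agrees with the coda implementation", {
  codaRhat <- function(ch) {
    unname(coda::gelman.diag(coda::mcmc.list(coda::mcmc(ch[, 1]),
                                             coda::mcmc(ch[, 2])),
                             autoburnin = FALSE)$psrf[1, 1])
  }
  # coda's estimator adds a (m+1)/m between-chain inflation and a
  # degrees-of-freedom correction, so exact agreement is only expected
  # under the convergence null
  set.seed(90)
  null_ch <- cbind(rnorm(5000), rnorm(5000))
  expect_equal(gelmanRhat(null_ch), codaRhat(null_ch), tolerance = 0.01)
  # and both flag clearly divergent chains
  div <- cbind(rnorm(1000, 0), rnorm(1000, 2))
  expect_gt(gelmanRhat(div), 1.1)
  expect_gt(codaRhat(div), 1.1)
})

test_that("sampler is bit-reproducible given seed, config and data", {
  sm <- summarizeDetections(makeAmbiguousFixture())
  cfg <- quickConfig(burnIn = 100L, keptIter = 300L, seed = 7L)
  f1 <- fitOccAbund(sm, cfg)
  f2 <- fitOccAbund(sm, cfg)
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  f3 <- fitOccAbund(sm, quickConfig(burnIn = 100L, keptIter = 300L,
                                    seed = 8L))
  expect_false(identical(posteriorDraws(f1), posteriorDraws(f3)))
})

test_that("saturated detection forces occupancy towards one", {
  ids <- sprintf("L%03d", 1:100)
  tr <- fullTrapGrid(ids)
  tr$possum_captures[tr$night == 1] <- 1L
  pe <- fullPelletGrid(ids)
  pe$presence <- 1L
  ds <- SurveyDataset(makeLocations(ids), tr, pe)
  f <- fitOccAbund(summarizeDetections(ds),
                   quickConfig(burnIn = 200L, keptIter = 800L))
  s <- posteriorSummary(f)
  expect_gt(s$mean[s$parameter == "psi"], 0.9)
})

test_that("zlambda equals lambda times psi draw by draw", {
  sim <- simulateSurvey(simDesign(nForest = 25L, nNonforest = 25L, seed = 9L))
  f <- fitOccAbund(summarizeDetections(sim$dataset),
                   quickConfig(strata = "by_habitat"))
  dr <- posteriorDraws(f)
  for (s in c("forest", "nonforest"))
    expect_identical(dr[, paste0("zlambda_", s)],
                     dr[, paste0("lambda_", s)] * dr[, paste0("psi_", s)])
})

test_that("posterior summaries are internally consistent", {
  sim <- simulateSurvey(simDesign(nForest = 30L, nNonforest = 0L, seed = 13L))
  f <- fitOccAbund(summarizeDetections(sim$dataset), quickConfig())
  s <- posteriorSummary(f)
  dr <- posteriorDraws(f)
  expect_true(all(s$ci_lower <= s$mean & s$mean <= s$ci_upper))
  expect_equal(s$cv, s$sd / s$mean)
  i <- match("psi", s$parameter)
  expect_equal(s$mean[i], mean(dr[, "psi"]))
  expect_equal(s$sd[i], sd(dr[, "psi"]))
})

test_that("all-zero data pushes occupancy towards zero as n grows", {
  psi_at <- function(n) {
    ids <- sprintf("L%03d", seq_len(n))
    ds <- SurveyDataset(makeLocations(ids), fullTrapGrid(ids),
                        fullPelletGrid(ids))
    f <- fitOccAbund(summarizeDetections(ds),
                     quickConfig(burnIn = 200L, keptIter = 800L),
                     fixP = c(p_trap = 0.8, p_pellet = 0.8),
                     fixLambda = 5)
    s <- posteriorSummary(f)
    s$mean[s$parameter == "psi"]
  }
  p10 <- psi_at(10); p40 <- psi_at(40); p120 <- psi_at(120)
  expect_gt(p10, p40)
  expect_gt(p40, p120)
  expect_lt(p120, 0.05)
})

test_that("stratified fit matches independent per-habitat fits (fixed p)", {
  sim <- simulateSurvey(simDesign(nForest = 40L, nNonforest = 40L,
                                  seed = 18L, missingLineFraction = 0))
  fixp <- c(p_trap = 0.55, p_pellet = 0.75)
  cfg <- quickConfig(burnIn = 500L, keptIter = 4000L, strata = "by_habitat")
  joint <- posteriorSummary(fitOccAbund(summarizeDetections(sim$dataset),
                                        cfg, fixP = fixp))
  ds <- sim$dataset
  for (hab in c("forest", "nonforest")) {
    ids <- names(habitats(ds))[habitats(ds) == hab]
    sub <- SurveyDataset(ds@locations[ds@locations$habitat == hab, ],
                         ds@traps[ds@traps$location_id %in% ids, ],
                         ds@pellets[ds@pellets$location_id %in% ids, ])
    solo <- posteriorSummary(fitOccAbund(
      summarizeDetections(sub),
      quickConfig(burnIn = 500L, keptIter = 4000L, seed = 77L),
      fixP = fixp))
    for (par in c("psi", "lambda")) {
      a <- joint$mean[joint$parameter == par & joint$stratum == hab]
      b <- solo$mean[solo$parameter == par]
      expect_equal(a, b, tolerance = 0.05, info = paste(par, hab))
    }
  }
})

test_that("dropping pellet information lowers the occupancy estimate on a
           benchmark where pellets add detections", {
  sim <- simulateSurvey(simDesign(nForest = 60L, nNonforest = 60L,
                                  seed = 23L))
  sm_both <- summarizeDetections(sim$dataset)
  f_both <- fitOccAbund(sm_both, quickConfig())
  f_traps <- fitOccAbund(sm_both, quickConfig(methods = "traps"))
  psi_both <- posteriorSummary(f_both)
  psi_traps <- posteriorSummary(f_traps)
  expect_lte(psi_traps$mean[psi_traps$parameter == "psi"],
             psi_both$mean[psi_both$parameter == "psi"] + 0.05)
})

test_that("non-convergence is flagged, not raised", {
  # 1 kept draw per chain cannot converge meaningfully; R-hat may be
  # extreme but the fit must return a flagged result
  sm <- summarizeDetections(makeAmbiguousFixture())
  f <- fitOccAbund(sm, modelConfig(nChains = 2L, burnIn = 5L, keptIter = 5L,
                                   seed = 2L))
  expect_s4_class(f, "PosteriorResult")
  expect_false(isConverged(f) && any(f@rhat > f@config@rhatThreshold))
})
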