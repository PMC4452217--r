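test_that("power routines agree with an independent noncentral-t oracle", {
  # requiredN: smallest n whose directly computed power reaches the target
  n <- requiredN(1.0, 1.0, alpha = 0.05, power = 0.8)
  expect_gte(directTTestPower(n, 1.0, 1.0), 0.8)
  expect_lt(directTTestPower(n - 1, 1.0, 1.0), 0.8)

  # detectableDelta: the returned delta attains the target power exactly
  for (pw in c(0.8, 0.95)) {
    d <- detectableDelta(300, 1.6, power = pw)
    expect_equal(directTTestPower(300, d, 1.6), pw, tolerance = 5e-4)
  }

  # sdFromAnchor: the recovered sd reproduces the anchoring statement
  s <- sdFromAnchor(225, 0.5, power = 0.8)
  expect_equal(directTTestPower(225, 0.5, s), 0.8, tolerance = 5e-4)
})

test_that("power function inversions are mutually consistent", {
  s <- sdFromAnchor(225, 0.5)
  expect_equal(requiredN(0.5, s), 225L)

  set.seed(20)
  for (i in 1:10) {
    d <- runif(1, 0.2, 2); sdv <- runif(1, 0.5, 4)
    n <- requiredN(d, sdv)
    expect_lte(detectableDelta(n, sdv), d + 1e-8)
  }

  # doubling the sd at fixed delta roughly quadruples n
  n1 <- requiredN(0.5, 1.5); n2 <- requiredN(0.5, 3.0)
  expect_equal(n2 / n1, 4, tolerance = 0.02)

  # a larger anchor n at fixed delta implies a larger recovered sd
  sds <- vapply(c(100, 225, 400, 800), function(n) sdFromAnchor(n, 0.5),
                numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("per-location costs reproduce the published schedule", {
  two <- costPerLocation(costSchedule(), "two_night")
  one <- costPerLocation(costSchedule(), "one_night")
  pick <- function(d, item) d$cost[d$item == item]
  expect_equal(pick(two, "labour"), 1080.00)
  expect_equal(pick(one, "labour"), 900.00)
  expect_equal(pick(two, "allowance"), 126.00)
  expect_equal(pick(one, "food"), 90.44)
  expect_equal(pick(two, "fixed"), 3278.00)
  expect_equal(pick(two, "total"), 4619.66)
  expect_equal(pick(one, "total"), 4352.44)
  expect_equal(pick(two, "total"), pick(two, "fixed") + pick(two, "variable"))

  zero <- costSchedule(vehiclePerLocation = 0, helicopterPerLocation = 0,
                       equipmentPerLocation = 0, labourRate = 0,
                       allowancePerPersonDay = 0, foodPerPersonDay = 0)
  expect_equal(costPerLocation(zero, "two_night")$cost,
               rep(0, 8))
})

test_that("the per-location saving is a variable-cost difference only", {
  base <- annualPlan(costSchedule())
  moved <- annualPlan(costSchedule(vehiclePerLocation = 10000,
                                   helicopterPerLocation = 1,
                                   equipmentPerLocation = 999))
  expect_equal(base$per_location$saving, moved$per_location$saving)
  expect_equal(base$annual_saving, moved$annual_saving)
})

test_that("annual plan arithmetic: field days, teams, savings", {
  plan <- annualPlan(costSchedule())
  expect_equal(unname(plan$field_days), c(813, 542))
  expect_equal(plan$available_days_per_team, 120)
  expect_equal(unname(plan$teams), c(7, 5))
  expect_equal(plan$per_location$saving, 267.22)
  expect_equal(plan$per_location$saving_percent, 100 * 267.22 / 4619.66)
  expect_equal(plan$annual_saving, 271 * 267.22)
  expect_equal(plan$annual_saving_rounded_100, 72400)
  expect_error(annualPlan(costSchedule(weatherLossFraction = 0.999,
                                       seasonDays = 1L)),
               "workable")
})

test_that("money formatting and exactness survive awkward rates", {
  expect_equal(formatMoney(4619.66), "$4,619.66")
  expect_equal(formatMoney(72416.62), "$72,416.62")
  # 22.61 * 6 has no exact binary representation; cents stay exact
  sched <- costSchedule()
  food6 <- costPerLocation(sched, "two_night")
  expect_equal(food6$cost[food6$item == "food"], 135.66)
  expect_identical(round(food6$cost[food6$item == "food"] * 100), 13566)
})
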