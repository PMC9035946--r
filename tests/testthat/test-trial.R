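test_that("population averages match an independent recomputation", {
  one <- data.frame(step = 0:3, day = (0:3) / 3, x = c(1, 2, 3, 4))
  pa <- populationAverage(list(one))
  expect_equal(pa$mean$x, one$x)
  expect_equal(pa$sd$x, rep(0, 4))
  two <- list(data.frame(step = 0:2, v = rep(2, 3)),
              data.frame(step = 0:2, v = rep(4, 3)))
  expect_equal(populationAverage(two)$mean$v, rep(3, 3))
  set.seed(5)
  rnd <- lapply(1:10, function(i)
    data.frame(step = 0:9, a = rnorm(10), b = runif(10)))
  pa <- populationAverage(rnd)
  for (col in c("a", "b")) for (r in 1:10) {
    vals <- vapply(rnd, function(d) d[[col]][r], 0)
    expect_equal(pa$mean[[col]][r], mean(vals))
    expect_equal(pa$sd[[col]][r], sd(vals))
  }
  expect_error(populationAverage(list(one, two[[1]])), "equal length")
})

test_that("quartile splits are contiguous, ordered, and sized by the remainder rule", {
  mk <- function(n) data.frame(patient_id = 1:n, exposure = runif(n))
  set.seed(8)
  q8 <- quartileSplit(mk(8))
  expect_equal(as.vector(table(q8$quartile)), rep(2L, 4))
  q411 <- quartileSplit(mk(411))
  expect_equal(as.vector(table(q411$quartile)), c(103L, 103L, 103L, 102L))
  for (k in 1:3)
    expect_lte(max(q411$exposure[q411$quartile == k]),
               min(q411$exposure[q411$quartile == k + 1]))
  expect_error(quartileSplit(mk(3)), "at least 4")
  # ties broken by patient id: equal exposures split deterministically
  tied <- data.frame(patient_id = 1:8, exposure = rep(1, 8))
  qt <- quartileSplit(tied)
  expect_identical(qt$quartile, rep(1:4, each = 2L))
})

test_that("exposure-response correlation handles monotone, null and degenerate data", {
  x <- 1:20
  expect_equal(exposureResponseCorrelation(x, 100 - 3 * x)$rho, -1)
  dg <- exposureResponseCorrelation(x, rep(5, 20))
  expect_identical(dg$degenerate, TRUE)
  expect_identical(dg$rho, 0)
  set.seed(10)
  nullr <- exposureResponseCorrelation(runif(1000), runif(1000))
  expect_lt(abs(nullr$rho), 0.1)
  expect_error(exposureResponseCorrelation(1:2, 1:2), "n >= 3")
  expect_error(exposureResponseCorrelation(rep(1, 5), 1:5), "constant")
})

test_that("the fold-change effect is exact on known means and its CI calibrates", {
  same <- rnorm(30, 50, 5)
  expect_equal(foldChangeEffect(same, same)$effect, 0)
  expect_equal(foldChangeEffect(rep(100, 10), rep(61, 10))$effect, -39)
  expect_error(foldChangeEffect(rep(0, 5), rep(1, 5)), "undefined")
  # bootstrap CI covers the true -39% effect at close to nominal rate
  set.seed(17)
  cover <- vapply(1:300, function(i) {
    ref <- rnorm(40, 100, 10)
    x2 <- rnorm(40, 61, 10)
    ci <- foldChangeEffect(ref, x2, nBoot = 400, seed = i)$ci
    ci[1] <= -39 && -39 <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.92)
})

test_that("calibration inverts a closed-form dose-response surrogate", {
  C0 <- 10; EC50 <- 15
  surrogate <- function(moa) {
    Imax <- moa@entries$Imax[1]
    ref <- suppressionFactor(C0, Imax, EC50)
    x2 <- suppressionFactor(2 * C0, Imax, EC50)
    100 * (x2 - ref) / ref
  }
  cal0 <- calibrateMoa(0, surrogate)
  expect_identical(cal0$Imax, 0)
  ImaxStar <- 0.63
  target <- surrogate(setSharedImax(defaultMoAMap(), ImaxStar))
  cal <- calibrateMoa(target, surrogate, tol = 0.01, maxIter = 25)
  expect_true(cal$converged)
  expect_lt(abs(cal$Imax - ImaxStar), 0.005)
  # a target beyond the Imax = 1 asymptote is reported as unreachable
  unreach <- calibrateMoa(-90, surrogate, tol = 0.5)
  expect_false(unreach$converged)
})

test_that("benchmark-dose search inverts the Hill curve analytically", {
  EC50 <- 15
  reduction <- function(C) 100 * C / (C + EC50)   # Imax = 1, hill = 1
  expect_identical(benchmarkDose(0, reduction)$bmd, 0)
  bmd10 <- benchmarkDose(10, reduction, tol = 0.01)
  expect_true(bmd10$converged)
  expect_equal(bmd10$bmd, EC50 / 9, tolerance = 0.01)
  bmd5 <- benchmarkDose(5, reduction, tol = 0.01)
  expect_lt(bmd5$bmd, bmd10$bmd)
  # unreachable target reports a bounded-search failure
  weak <- function(C) 20 * C / (C + EC50)
  expect_false(benchmarkDose(50, weak, Cmax = 1e3)$converged)
})

test_that("a homeostatic run stays in the OU stationary band", {
  p <- testPatient(90)
  sched <- TrialSchedule(scheduleEvents(), duration = 20, samplingDay = NA)
  ts <- runSimulation(p, sched, NULL)
  cfg <- defaultConfig()
  band <- 3 * cfg$ou$sigma / sqrt(2 * cfg$ou$theta)
  mus <- c(nB = cfg$pools$B, nMAC = p@features[["M"]], nDC = p@features[["DC"]],
           nNK = cfg$pools$NK)
  for (nm in names(mus))
    expect_true(all(abs(ts[[nm]] - mus[[nm]]) <= band + 3),
                label = sprintf("%s within stationary band", nm))
})

test_that("scheduled challenges enter the world at the exact step", {
  p <- testPatient(91)
  sched <- challengeSchedule(days = 20, duration = 22)
  ts <- runSimulation(p, sched, NULL)
  expect_true(all(ts$bacteria_units[ts$step < 60] == 0))
  expect_gt(ts$bacteria_units[ts$step == 60], 0)
  expect_error(
    runSimulation(p, TrialSchedule(
      scheduleEvents(day = 50, type = "VACCINE_DOSE", antigen = "hib"),
      duration = 40)),
    "duration")
})

test_that("trials build one endpoint row per patient and are seed-stable", {
  spec <- adultPopulationSpec()
  cohort <- generateCohort(1, spec, 11)
  sched <- TrialSchedule(scheduleEvents(day = 2, type = "VACCINE_DOSE",
                                        antigen = "tetanus"),
                         duration = 10, samplingDay = NA)
  r <- runTrial(cohort, sched, NULL)
  expect_identical(nrow(r@endpoints), 1L)
  # paired cohorts at exposure 0 vs 0 are identical
  c1 <- generateCohort(3, spec, 12)
  c2 <- generateCohort(3, spec, 12)
  rA <- runTrial(c1, sched, NULL)
  rB <- runTrial(c2, sched, constantExposure(0))
  expect_identical(rA@endpoints, rB@endpoints)
  expect_error(runTrial(new("PatientCohort", patients = list(),
                            masterSeed = 1L, label = "x"), sched), "empty")
})

test_that("distinct patient vectors yield distinct trajectories under one seed", {
  spec <- adultPopulationSpec()
  set.seed(70); pa <- samplePatient(spec)
  set.seed(71); pb <- samplePatient(spec)
  pa@seed <- 500L; pb@seed <- 500L   # same seed, different personalization
  sched <- TrialSchedule(scheduleEvents(day = 2, type = "VACCINE_DOSE",
                                        antigen = "hib"),
                         duration = 10, samplingDay = NA)
  a <- runSimulation(pa, sched, NULL)
  b <- runSimulation(pb, sched, NULL)
  expect_false(identical(a, b))
})

test_that("shipped study designs match the published trial layouts", {
  ea <- studyDesign("exposure_adult")
  expect_identical(ea$n, 100L)
  expect_equal(ea$schedule@events$day, c(20, 100))
  expect_true(all(ea$schedule@events$type == "BACTERIAL_CHALLENGE"))
  expect_equal(serumConcentration(ea$exposure, 0), 10)
  expect_equal(range(ea$spec@features[ea$spec@features$name == "Age",
                                      c("lower", "upper")]), c(18, 60))
  dc <- studyDesign("diphtheria_child")
  expect_identical(dc$spec@label, "child")
  expect_equal(nrow(dc$schedule@events), 2L)
  expect_equal(dc$schedule@samplingDay, dc$schedule@events$day[2] + 60)
  infl <- studyDesign("influenza")
  expect_identical(infl$n, 411L)
  expect_identical(infl$exposure, "patient")
})

test_that("delimited outputs round-trip with stable headers", {
  d <- data.frame(step = 0:2, day = (0:2) / 3, nB = c(1, 2, 3),
                  IL6 = c(0.5, 0.25, 0.125))
  tmp <- tempfile(fileext = ".csv")
  writeTimeseriesCsv(d, tmp)
  back <- read.csv(tmp)
  expect_identical(names(back),
                   c("step", "day", "quantity", "value", "patient_id"))
  expect_equal(back$value[back$quantity == "IL6"], d$IL6)
  ep <- data.frame(patient_id = 1:2, exposure = c(0, 10),
                   endpoint_IgG = c(pi, exp(1)))
  tmp2 <- tempfile(fileext = ".csv")
  writeEndpointsCsv(ep, tmp2)
  back2 <- read.csv(tmp2)
  expect_equal(back2$endpoint_IgG, ep$endpoint_IgG, tolerance = 1e-15)
  tmp3 <- tempfile(fileext = ".json")
  writeManifestJson(list(seed = 1L, hash = "abc"), tmp3)
  expect_identical(jsonlite::read_json(tmp3)$hash, "abc")
})
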