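test_that("serum concentration is a step-constant lookup", {
  ep <- ExposureProfile("PFOA", times = 0, conc = 10)
  expect_equal(serumConcentration(ep, c(0, 1, 500)), c(10, 10, 10))
  late <- ExposureProfile("PFOA", times = 30, conc = 20)
  expect_equal(serumConcentration(late, 29), 0)
  pw <- ExposureProfile("PFOA", times = c(0, 30), conc = c(5, 20))
  expect_equal(serumConcentration(pw, 29), 5)
  expect_equal(serumConcentration(pw, 30), 20)
  expect_error(serumConcentration(pw, -1), ">= 0")
})

test_that("the Hill suppression factor has the right landmarks and bounds", {
  expect_equal(suppressionFactor(0, Imax = 1, EC50 = 15), 1.0)
  expect_equal(suppressionFactor(15, Imax = 1, EC50 = 15, hill = 1), 0.5)
  expect_equal(suppressionFactor(1e12, Imax = 0.8, EC50 = 15), 0.2,
               tolerance = 1e-9)
  # factor in [1 - Imax, 1], non-increasing, over a wide log grid
  C <- 15 * 10^seq(-3, 3, length.out = 61)
  for (Imax in c(0.3, 1)) for (h in c(0.7, 1, 2)) {
    f <- suppressionFactor(C, Imax, 15, h)
    expect_true(all(f >= 1 - Imax - 1e-12 & f <= 1 + 1e-12))
    expect_true(all(diff(f) <= 1e-12))
  }
  expect_error(suppressionFactor(-1, 1, 15), ">= 0")
  expect_error(suppressionFactor(1, 2, 15), "Imax")
})

test_that("the shipped MoA map covers exactly the documented targets", {
  moa <- defaultMoAMap()
  e <- moa@entries
  cyt <- sort(e$species[e$target == "CYTOKINE_SECRETION"])
  expect_equal(cyt, sort(c("IL6", "TNFA", "IL4", "IL8", "IL18", "IFNG", "IL10")))
  expect_setequal(e$target,
                  c("CYTOKINE_SECRETION", "B_POOL_MU", "THYMIC_OUTPUT",
                    "MAST_GROWTH"))
  expect_true(all(c("PFOA", "PFOS") %in% names(moa@potency)))
})

test_that("exposure multipliers match an independent Hill evaluation", {
  moa <- defaultMoAMap()
  zero <- applyExposure(constantExposure(0), moa, t = 10)
  expect_true(all(unlist(zero$cytokine) == 1))
  expect_identical(c(zero$bPoolMu, zero$thymicOutput, zero$mastGrowth),
                   c(1, 1, 1))
  ep <- constantExposure(15)
  m <- applyExposure(ep, moa, t = 0)
  e <- moa@entries
  for (i in seq_len(nrow(e))) {
    want <- 1 - e$Imax[i] * 15^e$hill[i] / (15^e$hill[i] + e$EC50[i]^e$hill[i])
    got <- switch(e$target[i],
                  CYTOKINE_SECRETION = m$cytokine[[e$species[i]]],
                  B_POOL_MU = m$bPoolMu,
                  THYMIC_OUTPUT = m$thymicOutput,
                  MAST_GROWTH = m$mastGrowth)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # untargeted species untouched; PFOS potency scales the concentration
  expect_equal(m$cytokine[["IL2"]], 1)
  mPfos <- applyExposure(constantExposure(10, "PFOS"), moa, t = 0)
  wantPfos <- 1 - e$Imax[1] * 15 / (15 + e$EC50[1])  # C = 10 * 1.5
  expect_equal(mPfos$cytokine[[e$species[1]]], wantPfos, tolerance = 1e-12)
  expect_error(applyExposure(constantExposure(1, "DDT"), moa, 0),
               "not in MoA map")
})

test_that("zero exposure is bit-identical to no exposure", {
  p <- testPatient(77)
  sched <- TrialSchedule(scheduleEvents(day = 3, type = "VACCINE_DOSE",
                                        antigen = "tetanus"),
                         duration = 15, samplingDay = NA)
  a <- runSimulation(p, sched, NULL)
  b <- runSimulation(p, sched, constantExposure(0), moa = defaultMoAMap())
  expect_identical(a, b)
})

test_that("saturating IL-6 suppression removes all IL-6 secretion", {
  moa <- MoAMap(data.frame(target = "CYTOKINE_SECRETION", species = "IL6",
                           Imax = 1, EC50 = 1e-6, hill = 1),
                potency = c(PFOA = 1))
  p <- testPatient(78)
  sched <- fastVaccineSchedule()
  base <- runSimulation(p, sched, NULL, moa = moa)
  supp <- runSimulation(p, sched, constantExposure(100), moa = moa)
  # with IL-6 deltas suppressed to ~0 the field can only decay from baseline
  # (the Hill factor at C >> EC50 is O(EC50/C), not exactly zero)
  decayBound <- supp$IL6[1] * 2^(-(supp$step) / defaultConfig()$fields$halfLife)
  expect_true(all(supp$IL6 <= decayBound + 1e-3))
  expect_gt(max(base$IL6), max(supp$IL6))
})
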