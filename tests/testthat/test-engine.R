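test_that("the OU step matches its closed form and stationary moments", {
  op <- OUParams(mu = 100, theta = 0.2, sigma = 0)
  expect_equal(ouStep(100, op), 100)
  expect_equal(ouStep(100 + 8, op, dt = 2, round = FALSE),
               100 + 8 * exp(-0.4), tolerance = 1e-12)
  set.seed(14)
  op <- OUParams(mu = 500, theta = 0.1, sigma = 2)
  n <- 1e5
  x <- numeric(n); x[1] <- 500
  for (i in 2:n) x[i] <- ouStep(x[i - 1], op, round = FALSE)
  statVar <- 2^2 / (2 * 0.1)
  # stationary mean within 3 standard errors (accounting for autocorrelation)
  ess <- n * (1 - exp(-0.1)) / (1 + exp(-0.1))
  expect_lt(abs(mean(x) - 500), 3 * sqrt(statVar / ess))
  expect_lt(abs(var(x) - statVar) / statVar, 0.1)
})

test_that("haematopoiesis restores a depleted lineage towards its mean", {
  cfg <- defaultConfig(list(ou = list(theta = 0.5, sigma = 0)))
  set.seed(31)
  st <- initState(cfg)
  ag <- st$agents
  bIdx <- which(ag$type == immunotox:::.typeCode("B"))
  drop <- rep(FALSE, length(ag$type))
  drop[bIdx[1:60]] <- TRUE                  # deplete half the B pool
  st$agents <- immunotox:::.subsetAgents(ag, !drop)
  for (i in 1:20) stepWorld(st)
  nB <- sum(st$agents$type == immunotox:::.typeCode("B"))
  expect_lt(abs(nB - 120) / 120, 0.05)
})

test_that("the site schedule permutes rules and actors uniformly and reproducibly", {
  rules <- list(list(name = "a", actors = 1:4),
                list(name = "b", actors = 5:6),
                list(name = "c", actors = 7L))
  set.seed(8); s1 <- buildSiteSchedule(rules)
  set.seed(8); s2 <- buildSiteSchedule(rules)
  expect_identical(s1, s2)
  expect_setequal(s1$ruleOrder, 1:3)
  expect_setequal(s1$actorOrders[[1]], 1:4)
  set.seed(42)
  n <- 3000
  keys <- replicate(n, paste(buildSiteSchedule(rules)$ruleOrder, collapse = ""))
  tab <- table(keys)
  expect_length(tab, 6L)  # all 3! orderings occur
  expect_true(all(abs(tab / n - 1 / 6) < 3 * sqrt((1 / 6) * (5 / 6) / n) + 0.005))
})

test_that("site interactions follow first-success Bernoulli semantics", {
  mkRule <- function(p, nA = 1, nB = 1, consumes = FALSE)
    list(name = "r", actors = seq_len(nA), partners = 100 + seq_len(nB),
         prob = if (is.matrix(p)) p else matrix(p, nA, nB),
         consumes = consumes)
  set.seed(1)
  expect_equal(nrow(executeSiteInteractions(list(mkRule(0, 3, 3)))), 0L)
  # p = 1, 2 actors, 3 partners, non-consuming: each actor succeeds once
  ev <- executeSiteInteractions(list(mkRule(1, 2, 3)))
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$actor, 1:2)
  # consuming rule with a single partner: only one actor can succeed
  ev2 <- executeSiteInteractions(list(mkRule(1, 2, 1, consumes = TRUE)))
  expect_equal(nrow(ev2), 1L)
  # 1 actor, 2 partners, p = 0.5: P(at least one event) = 0.75
  set.seed(99)
  n <- 5e4
  hits <- vapply(seq_len(n), function(i)
    nrow(executeSiteInteractions(list(mkRule(0.5, 1, 2)))) > 0, TRUE)
  expect_lt(abs(mean(hits) - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("antigen presentation respects thresholds, pathways and enumeration", {
  ap <- AffinityParams(l = 6, dMin = 6, alpha = 0.7, pMax = 1)
  set.seed(12)
  # peptide identical to the MHC string: d = 0 < dMin, never presented
  expect_true(is.na(processAndPresent(5L, mhcI = 9L, mhcII = 5L,
                                      "ENDOCYTIC", ap)))
  # perfect complement at pMax = 1: always presented, complex is the XOR
  comp <- bitwXor(5L, 63L)
  expect_identical(processAndPresent(comp, mhcI = 9L, mhcII = 5L,
                                     "ENDOCYTIC", ap), bitwXor(5L, comp))
  expect_error(processAndPresent(1L, mhcI = integer(0), mhcII = 5L,
                                 "CYTOSOLIC", ap), "lacks MHC")
  # feasible pair count equals exhaustive enumeration at l = 6
  ap2 <- AffinityParams(l = 6, dMin = 4, alpha = 0.5, pMax = 1)
  peptides <- c(3L, 40L, 63L, 21L)
  mhc <- c(9L, 54L)
  want <- 0L
  for (m in mhc) for (p in peptides)
    if (oracleHamming(m, p, 6) >= 4) want <- want + 1L
  expect_identical(presentablePairs(peptides, mhc, ap2), want)
})

test_that("clonal expansion respects the Hayflick limit and the tree bound", {
  expect_identical(clonalExpansion(6, 6), 0L)
  expect_identical(clonalExpansion(0, 6), 2L)
  h <- 5L
  cells <- 0L  # one founder, duplication counts only
  divisions <- 0L
  repeat {
    can <- which(clonalExpansion(cells, h) > 0L)
    if (!length(can)) break
    g <- cells[can[1]]
    cells <- c(cells[-can[1]], g + 1L, g + 1L)
    divisions <- divisions + 1L
  }
  expect_identical(divisions, 31L)  # 2^h - 1 internal nodes of the full tree
  expect_true(all(cells == h))
})

test_that("thymic education equals exhaustive brute force", {
  l <- 8L
  mhcSet <- c(23L, 200L)
  self <- c(90L, 170L, 5L)
  thetaPos <- 3L; thetaNeg <- 7L
  all256 <- 0:255
  keepPos <- thymusPositive(all256, mhcSet, thetaPos, l)
  keepNeg <- thymusNegative(all256, self, thetaNeg, l)
  for (r in all256) {
    dPos <- max(vapply(mhcSet, function(m) oracleHamming(r, m, l), 0))
    dNeg <- max(vapply(self, function(m) oracleHamming(r, m, l), 0))
    expect_identical(keepPos[r + 1], dPos >= thetaPos)
    expect_identical(keepNeg[r + 1], dNeg < thetaNeg)
  }
  surv <- thymusEducation(all256, mhcSet, self, thetaPos, thetaNeg, l)
  expect_identical(surv, all256[keepPos & keepNeg])
  # edge cases
  expect_identical(thymusEducation(integer(0), mhcSet, self, 3, 7, l),
                   integer(0))
  expect_identical(thymusEducation(all256, mhcSet, self, 0, l + 1, l), all256)
  expect_error(thymusPositive(1L, integer(0), 3, l), "non-empty")
  expect_identical(thymusNegative(7L, integer(0), 5, l), TRUE)
  # larger repertoire at l = 10: oracle equivalence on the same inputs
  set.seed(6)
  rep10 <- sampleRepertoire(1e4, 10)
  mhc10 <- sampleRepertoire(3, 10)
  self10 <- sampleRepertoire(6, 10)
  surv10 <- thymusEducation(rep10, mhc10, self10, 4, 9, 10)
  bf <- rep10[vapply(rep10, function(r) {
    max(vapply(mhc10, function(m) oracleHamming(r, m, 10), 0)) >= 4 &&
      max(vapply(self10, function(m) oracleHamming(r, m, 10), 0)) < 9
  }, TRUE)]
  expect_identical(surv10, bf)
})

test_that("an empty world is unchanged by a step except for the clock", {
  pools0 <- as.list(setNames(rep(0, 11),
                             c("B", "TH1", "TH2", "TC", "TREG", "NK", "MONO",
                               "MAC", "DC", "MAST", "NEU")))
  base0 <- as.list(setNames(rep(0, 15), cytokineSpecies()))
  cfg <- defaultConfig(list(pools = pools0, cytBaseline = base0,
                            ou = list(theta = 0.1, sigma = 0)))
  set.seed(2)
  st <- initState(cfg)
  before <- snapshotState(st)
  stepWorld(st)
  expect_identical(snapshotState(st), before)
  expect_identical(st$clock, 1L)
})

test_that("an uninitialized state is rejected", {
  st <- new.env()
  expect_error(stepWorld(st), "not initialized")
})

test_that("a full run is a pure function of patient and config", {
  p <- testPatient(55)
  sched <- TrialSchedule(scheduleEvents(day = c(2, 6), type = "VACCINE_DOSE",
                                        antigen = "hib"),
                         duration = 12, samplingDay = NA)
  a <- runSimulation(p, sched, NULL)
  b <- runSimulation(p, sched, NULL)
  expect_identical(a, b)
})

test_that("without matching lymphocytes a PAMP-free antigen just decays", {
  cfg <- defaultConfig(list(
    affinity = list(dMin = 8, alpha = 0.7, pMax = 0),
    mhcAffinity = list(dMin = 6, alpha = 0.7, pMax = 0),
    pNonPamp = 0))
  p <- testPatient(60)
  sched <- TrialSchedule(
    scheduleEvents(day = 1, type = "BACTERIAL_CHALLENGE", antigen = "bacteria",
                   dose = 600, pamp = FALSE),
    duration = 25, samplingDay = NA)
  ts <- runSimulation(p, sched, NULL, config = cfg)
  # 24 days = 8 antigen half-lives: under 1% of the bolus remains
  expect_lt(tail(ts$bacteria_units, 1), 6)
  expect_true(all(ts$bacteria_IgM == 0))
  expect_true(all(ts$bacteria_IgG == 0))
})

test_that("interactions never couple entities at different sites", {
  pools0 <- as.list(setNames(rep(0, 11),
                             c("B", "TH1", "TH2", "TC", "TREG", "NK", "MONO",
                               "MAC", "DC", "MAST", "NEU")))
  pools0$DC <- 2  # homeostasis keeps exactly the two tracer dendritic cells
  cfg <- defaultConfig(list(pools = pools0, pAspecific = 1,
                            ou = list(theta = 0.1, sigma = 0)))
  restingCode <- match("RESTING", cellStates())
  for (seed in 1:20) {
    set.seed(seed)
    st <- initState(cfg)
    st$agents <- immunotox:::.makeAgents(2L, "DC", pos = c(0L, 40L),
                                         halfLife = 1e9)
    ad <- antigenDef("bacteria", cfg)
    st$antigens[["bacteria"]] <- list(epitope = ad$epitope,
                                      peptides = ad$peptides, pamp = TRUE,
                                      pos = rep(0L, 30L))
    stepWorld(st)
    # the dendritic cell far from the antigen can never have interacted
    expect_identical(st$agents$state[2], restingCode)
  }
})

test_that("agents never exceed the Hayflick limit during a response", {
  p <- testPatient(61)
  cfg <- defaultConfig()
  sched <- fastVaccineSchedule()
  set.seed(p@seed)
  st <- initState(cfg, hlaI = p@hlaI, hlaII = p@hlaII)
  ad <- antigenDef("diphtheria", cfg)
  injectAntigen(st, "diphtheria", ad$epitope, ad$peptides, ad$pamp, ad$dose)
  thyCode <- match("THYMUS", compartments())
  bCode <- match("B", cellTypes())
  for (i in 1:60) {
    stepWorld(st)
    expect_true(all(st$agents$dup <= cfg$hayflick))
    # compartment containment: the thymus only ever holds maturing T cells
    inThy <- st$agents$comp == thyCode
    expect_false(any(st$agents$type[inThy] == bCode))
    expect_true(all(st$agents$type[inThy] %in%
                      match(c("TH1", "TH2", "TC"), cellTypes())))
  }
})

test_that("plasma-cell secretion accumulates linearly without decay", {
  pools0 <- as.list(setNames(rep(0, 11),
                             c("B", "TH1", "TH2", "TC", "TREG", "NK", "MONO",
                               "MAC", "DC", "MAST", "NEU")))
  cfg <- defaultConfig(list(pools = pools0, igHalfLife = 1e12, pIgA = 0,
                            ou = list(theta = 0.1, sigma = 0)))
  set.seed(5)
  st <- initState(cfg)
  st$agents <- immunotox:::.makeAgents(5L, "PLB", pos = 0:4, receptor = 100L,
                                       halfLife = 1e9, state = "ACTIVE",
                                       isotype = match("IgG", igIsotypes()),
                                       uid = 1:5)
  for (i in 1:7) stepWorld(st)
  # 5 cells x rate x 7 steps, all in one clonotype
  expect_equal(sum(st$ig$conc), 5 * cfg$igRate * 7, tolerance = 1e-9)
  expect_identical(st$ig$paratope, 100L)
})

test_that("serialized trial outputs are byte-identical across repeat runs", {
  cohort <- generateCohort(2, adultPopulationSpec(), 21)
  sched <- TrialSchedule(scheduleEvents(day = 2, type = "VACCINE_DOSE",
                                        antigen = "hib"),
                         duration = 8, samplingDay = NA)
  f1 <- tempfile(); f2 <- tempfile()
  for (f in c(f1, f2)) {
    r <- runTrial(cohort, sched, NULL, keepSeries = TRUE)
    writeTimeseriesCsv(r@series, paste0(f, "_ts.csv"))
    writeEndpointsCsv(r@endpoints, paste0(f, "_ep.csv"))
  }
  expect_identical(readLines(paste0(f1, "_ts.csv")),
                   readLines(paste0(f2, "_ts.csv")))
  expect_identical(readLines(paste0(f1, "_ep.csv")),
                   readLines(paste0(f2, "_ep.csv")))
})
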