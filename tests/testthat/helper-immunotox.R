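# Shared fixtures: all built in code at test time.

# independent bit-string oracle: distances via character comparison
oracleBits <- function(x, l) {
  vapply(x, function(v) paste(rev((v %/% 2^(0:(l - 1))) %% 2), collapse = ""),
         character(1))
}
oracleHamming <- function(a, b, l) {
  sa <- strsplit(oracleBits(a, l), "")[[1]]
  sb <- strsplit(oracleBits(b, l), "")[[1]]
  sum(sa != sb)
}

# a small patient with a fixed seed, for engine-level tests
testPatient <- function(seed = 101L, spec = adultPopulationSpec()) {
  set.seed(seed)
  p <- samplePatient(spec)
  p@seed <- as.integer(seed)
  p
}

# compressed single-dose schedule for fast exposure contrasts (peak endpoint)
fastVaccineSchedule <- function() {
  TrialSchedule(scheduleEvents(day = 5, type = "VACCINE_DOSE",
                               antigen = "diphtheria"),
                duration = 40, samplingDay = NA)
}

# peak antigen-specific IgG of one patient run
peakIgG <- function(patient, schedule, exposure = NULL,
                    moa = defaultMoAMap(), config = defaultConfig()) {
  ts <- runSimulation(patient, schedule, exposure, config, moa)
  ant <- schedule@events$antigen[1]
  max(ts[[paste0(ant, "_IgG")]])
}
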