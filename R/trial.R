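# In silico trial orchestration: per-patient runs, cohort trials, and the
# endpoint table. Exposed-vs-unexposed contrasts use common random numbers:
# paired cohorts share per-patient seeds so arms differ only through the
# exposure effect.

#' Result of one in silico trial
#'
#' @slot endpoints data.frame, one row per patient: \code{patient_id},
#'   \code{exposure} (ng/ml), \code{endpoint_IgM/IgG/IgA} (titre at the
#'   sampling day or peak), \code{peak_IgG}.
#' @slot series list of per-patient time-series data.frames (possibly empty
#'   when not kept).
#' @slot manifest list: master seed, schedule summary, config hash, version.
#' @export
setClass("TrialResult",
  representation(endpoints = "data.frame", series = "list", manifest = "list"))

setMethod("show", "TrialResult", function(object) {
  cat(sprintf("TrialResult: %d patients, mean endpoint IgG %.4g\n",
              nrow(object@endpoints), mean(object@endpoints$endpoint_IgG)))
})

.patientPools <- function(patient, spec = NULL) {
  f <- patient@features
  scale <- 1
  list(TH1 = f[["Th1"]], TH2 = f[["Th2"]], TC = f[["TC"]],
       TREG = f[["Treg"]], MAC = f[["M"]], DC = f[["DC"]])
}

.patientBaselines <- function(patient) {
  f <- patient@features
  c(IL1 = f[["IL1"]], IL2 = f[["IL2"]], IL10 = f[["IL10"]],
    IL12 = f[["IL12"]], IL17 = f[["IL17A"]], IL23 = f[["IL23"]],
    IFNA1 = f[["IFN1A"]], IFNB1 = f[["IFN1B"]], IFNG = f[["IFNG"]],
    TNFA = f[["TNF"]], TGFB = f[["TGFB"]])
}

#' Simulate one virtual patient through a trial schedule
#'
#' Seeds the RNG with the patient's private seed, initializes the engine from
#' the patient vector (lineage pools, cytokine baselines, HLA haplotypes,
#' baseline IgG), injects the scheduled antigens into the secondary organ at
#' their scheduled steps (8-hour steps, 3 per day), applies the exposure at
#' every step and returns the full tracked time series. Each patient also
#' receives a lognormally jittered isotype-switch (IL-4) threshold drawn
#' under their seed, representing between-patient class-switch sensitivity;
#' identical across paired arms. Deterministic given the patient.
#'
#' @param patient a \code{\link{VirtualPatient}}.
#' @param schedule a \code{\link{TrialSchedule}}.
#' @param exposure an \code{\link{ExposureProfile}}, \code{NULL} (none), or
#'   the string \code{"patient"} to use the patient's serum exposure feature
#'   as a constant profile.
#' @param config engine configuration; \code{\link{defaultConfig}()} by
#'   default.
#' @param moa \code{\link{MoAMap}} used when an exposure is active.
#' @param poolScale extra scale factor on lineage pools (population specs
#'   use it for child cohorts).
#' @return data.frame time series: \code{step}, \code{day}, then one column
#'   per tracked quantity (cell counts, cytokine totals, antigen units and
#'   specific titres).
#' @export
runSimulation <- function(patient, schedule, exposure = NULL,
                          config = defaultConfig(), moa = defaultMoAMap(),
                          poolScale = 1) {
  if (nrow(schedule@events) &&
      any(schedule@events$day > schedule@duration))
    stop("schedule events beyond trial duration", call. = FALSE)
  if (identical(exposure, "patient"))
    exposure <- constantExposure(patient@features[["PFOA"]])
  set.seed(patient@seed)
  # biological heterogeneity: per-patient isotype-switch sensitivity
  # (lognormal around the configured threshold, shared across paired arms)
  config$il4Threshold <- config$il4Threshold * exp(rnorm(1, 0, 0.35))
  pools <- .patientPools(patient)
  pools <- lapply(pools, function(x) x * poolScale)
  pools$B <- config$pools$B * poolScale
  st <- initState(config, hlaI = patient@hlaI, hlaII = patient@hlaII,
                  pools = pools, baselines = .patientBaselines(patient),
                  igG0 = patient@features[["IgG"]])
  useCrnStreams(st, patient@seed)
  nSteps <- dayToStep(schedule@duration, config)
  ev <- schedule@events
  evStep <- if (nrow(ev)) dayToStep(ev$day, config) else integer(0)
  antigenIds <- unique(ev$antigen)
  # pre-register scheduled antigens so titre columns exist from step 0
  for (aid in antigenIds) {
    ad <- antigenDef(aid, config)
    st$antigens[[aid]] <- list(epitope = ad$epitope, peptides = ad$peptides,
                               pamp = ad$pamp, pos = integer(0))
  }
  injectEvents <- function(hit) {
    for (i in hit) {
      ad <- antigenDef(ev$antigen[i], config)
      dose <- if (is.na(ev$dose[i])) ad$dose else as.integer(ev$dose[i])
      pamp <- if (is.na(ev$pamp[i])) ad$pamp else isTRUE(ev$pamp[i])
      injectAntigen(st, ev$antigen[i], ad$epitope, ad$peptides, pamp, dose)
    }
  }
  injectEvents(which(evStep == 0L))
  rec <- vector("list", nSteps + 1L)
  rec[[1L]] <- snapshotState(st, antigenIds)
  for (s in seq_len(nSteps)) {
    # an event on day d enters the world during the step that ends at d
    injectEvents(which(evStep == s))
    stepWorld(st, exposure = exposure, moa = moa)
    rec[[s + 1L]] <- snapshotState(st, antigenIds)
  }
  m <- do.call(rbind, rec)
  data.frame(step = 0:nSteps, day = (0:nSteps) / config$stepsPerDay, m,
             check.names = FALSE)
}

#' Run an in silico trial over a cohort
#'
#' Simulates every patient under the schedule and exposure and builds the
#' endpoint table: the antigen-specific IgG titre of the schedule's primary
#' antigen at the sampling day (or the peak titre when no sampling day is
#' set), together with IgM/IgA and the peak IgG.
#'
#' @param cohort a \code{\link{PatientCohort}} (non-empty).
#' @param schedule a \code{\link{TrialSchedule}}.
#' @param exposure \code{NULL}, an \code{\link{ExposureProfile}} shared by
#'   all patients, or \code{"patient"} for per-patient constant exposure.
#' @param config engine configuration.
#' @param moa \code{\link{MoAMap}}.
#' @param poolScale lineage-pool scale factor (see
#'   \code{\link{runSimulation}}).
#' @param keepSeries keep every per-patient series in the result?
#' @return A \code{\link{TrialResult}}.
#' @export
runTrial <- function(cohort, schedule, exposure = NULL,
                     config = defaultConfig(), moa = defaultMoAMap(),
                     poolScale = 1, keepSeries = FALSE) {
  if (!length(cohort@patients)) stop("cohort is empty", call. = FALSE)
  primary <- if (nrow(schedule@events)) tail(schedule@events$antigen, 1L)
             else NA_character_
  rows <- vector("list", length(cohort@patients))
  series <- if (keepSeries) vector("list", length(cohort@patients)) else list()
  for (i in seq_along(cohort@patients)) {
    p <- cohort@patients[[i]]
    ts <- runSimulation(p, schedule, exposure, config, moa, poolScale)
    expo <- if (identical(exposure, "patient")) p@features[["PFOA"]]
            else if (is.null(exposure)) 0
            else max(serumConcentration(exposure, ts$step))
    ig <- function(iso) {
      col <- paste0(primary, "_", iso)
      if (!col %in% names(ts)) return(c(end = 0, peak = 0))
      v <- ts[[col]]
      endv <- if (is.na(schedule@samplingDay)) max(v)
              else v[which.min(abs(ts$day - schedule@samplingDay))]
      c(end = endv, peak = max(v))
    }
    gm <- ig("IgM"); gg <- ig("IgG"); ga <- ig("IgA")
    rows[[i]] <- data.frame(patient_id = i, exposure = expo,
                            endpoint_IgM = gm["end"], endpoint_IgG = gg["end"],
                            endpoint_IgA = ga["end"], peak_IgG = gg["peak"])
    if (keepSeries) series[[i]] <- ts
  }
  endpoints <- do.call(rbind, rows)
  rownames(endpoints) <- NULL
  manifest <- list(masterSeed = cohort@masterSeed, n = nrow(endpoints),
                   antigen = primary,
                   samplingDay = schedule@samplingDay,
                   duration = schedule@duration,
                   version = as.character(utils::packageVersion("immunotox")))
  new("TrialResult", endpoints = endpoints, series = series,
      manifest = manifest)
}
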