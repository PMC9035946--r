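# Trial schedules: bacterial challenges and vaccine doses injected into the
# secondary organ at scheduled days, plus the endpoint sampling day.

#' Challenge/vaccination schedule for one trial
#'
#' @slot events data.frame: \code{day}, \code{type}
#'   (\code{"BACTERIAL_CHALLENGE"} or \code{"VACCINE_DOSE"}), \code{antigen}
#'   id from the configured catalogue, \code{dose} (units; NA = catalogue
#'   default), \code{pamp} (logical; NA = catalogue default).
#' @slot duration trial length in days.
#' @slot samplingDay endpoint day for the antibody titre (NA = use the peak).
#' @export
setClass("TrialSchedule",
  representation(events = "data.frame", duration = "numeric",
                 samplingDay = "numeric"))

setValidity("TrialSchedule", function(object) {
  e <- object@events
  msg <- character()
  if (nrow(e) && !all(c("day", "type", "antigen", "dose", "pamp") %in% names(e)))
    return("events needs columns day, type, antigen, dose, pamp")
  if (nrow(e) && any(e$day > object@duration))
    msg <- c(msg, "event days must lie within the trial duration")
  if (nrow(e) && !all(e$type %in% c("BACTERIAL_CHALLENGE", "VACCINE_DOSE")))
    msg <- c(msg, "unknown event type")
  if (!is.na(object@samplingDay) && object@samplingDay > object@duration)
    msg <- c(msg, "samplingDay must lie within the trial duration")
  if (length(msg)) msg else TRUE
})

#' @param events data.frame of events (see slots); zero rows allowed.
#' @param duration days.
#' @param samplingDay endpoint day (NA = peak titre).
#' @rdname TrialSchedule-class
#' @export
TrialSchedule <- function(events = scheduleEvents(), duration, samplingDay = NA) {
  new("TrialSchedule", events = events, duration = as.numeric(duration),
      samplingDay = as.numeric(samplingDay))
}

#' Build a schedule event table
#' @param day,type,antigen,dose,pamp vectors (recycled); see
#'   \code{\link{TrialSchedule}}.
#' @export
scheduleEvents <- function(day = numeric(0), type = character(0),
                           antigen = character(0), dose = NA, pamp = NA) {
  n <- length(day)
  data.frame(day = day, type = rep_len(type, n), antigen = rep_len(antigen, n),
             dose = rep_len(dose, n), pamp = rep_len(pamp, n),
             stringsAsFactors = FALSE)
}

setMethod("show", "TrialSchedule", function(object) {
  cat(sprintf("TrialSchedule: %d event(s) over %g days, endpoint day %s\n",
              nrow(object@events), object@duration,
              ifelse(is.na(object@samplingDay), "peak",
                     format(object@samplingDay))))
  if (nrow(object@events)) {
    for (i in seq_len(nrow(object@events)))
      cat(sprintf("  day %3g: %s (%s)\n", object@events$day[i],
                  object@events$type[i], object@events$antigen[i]))
  }
})

#' Two identical bacterial challenges
#'
#' The generic exposure-study design: challenges at day 20 and day 100, run
#' to day 130 with the endpoint at the peak.
#' @param days challenge days.
#' @param duration trial length in days.
#' @export
challengeSchedule <- function(days = c(20, 100), duration = max(days) + 30) {
  TrialSchedule(scheduleEvents(day = days, type = "BACTERIAL_CHALLENGE",
                               antigen = "bacteria"),
                duration = duration, samplingDay = NA)
}

#' Two-dose vaccination schedule
#'
#' @param antigen vaccine antigen id.
#' @param days dose days.
#' @param samplingOffset endpoint: days after the second dose.
#' @export
twoDoseSchedule <- function(antigen = "diphtheria", days = c(10, 38),
                            samplingOffset = 60) {
  TrialSchedule(scheduleEvents(day = days, type = "VACCINE_DOSE",
                               antigen = antigen),
                duration = days[2] + samplingOffset,
                samplingDay = days[2] + samplingOffset)
}
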