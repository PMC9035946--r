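# Shipped study designs mirroring the published in silico experiments:
# the adult exposure study (two cohorts of 100, 10 ng/ml vs unexposed,
# bacterial challenges at day 20 and day 100), the child two-dose diphtheria
# study used for calibration and the 2-fold exposure contrast, and the
# influenza study (411 patients, per-patient exposure, quartile analysis).

#' Shipped study designs
#'
#' @param name one of \code{"exposure_adult"}, \code{"diphtheria_child"},
#'   \code{"influenza"}.
#' @return List: \code{spec} (\code{\link{PopulationSpec}}), \code{schedule}
#'   (\code{\link{TrialSchedule}}), \code{n}, \code{exposure} (profile,
#'   \code{NULL}, or \code{"patient"}), and for the diphtheria study
#'   \code{C0}, the reference serum concentration of the 2-fold contrast.
#' @examples
#' s <- studyDesign("exposure_adult")
#' s$schedule
#' @export
studyDesign <- function(name = c("exposure_adult", "diphtheria_child",
                                 "influenza")) {
  name <- match.arg(name)
  switch(name,
    exposure_adult = list(
      name = name,
      spec = adultPopulationSpec(),
      schedule = challengeSchedule(c(20, 100)),
      n = 100L,
      exposure = constantExposure(10, "PFOA")),
    diphtheria_child = list(
      name = name,
      spec = childPopulationSpec(),
      schedule = twoDoseSchedule("diphtheria", days = c(10, 38),
                                 samplingOffset = 60),
      n = 100L,
      C0 = 10,
      exposure = constantExposure(10, "PFOA")),
    influenza = list(
      name = name,
      spec = adultPopulationSpec(),
      schedule = TrialSchedule(
        scheduleEvents(day = 10, type = "VACCINE_DOSE", antigen = "h1n1"),
        duration = 50, samplingDay = 40),
      n = 411L,
      exposure = "patient"))
}
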