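# Calibration and benchmark-dose search. Both are bisection searches on a
# monotone simulator response: calibration tunes the shared maximal
# suppression Imax of the mechanism-of-action map until the simulated
# 2-fold-exposure effect on the antibody endpoint matches a target percent
# difference; the benchmark dose inverts the exposure-response curve at a
# predetermined percent reduction in antibody response (e.g. 5 or 10%).

#' Set the shared maximal suppression of a mechanism-of-action map
#' @param moa a \code{\link{MoAMap}}.
#' @param Imax value in [0, 1] written to every entry.
#' @export
setSharedImax <- function(moa, Imax) {
  e <- moa@entries
  e$Imax <- Imax
  initialize(moa, entries = e)
}

#' Paired-cohort fold-change effect function of a MoA map
#'
#' Builds the closure used by \code{\link{calibrateMoa}}: a fixed cohort
#' (common random numbers across arms and across calls) is run under constant
#' serum exposure \code{C0} and \code{2 * C0}, and the fold-change effect on
#' the endpoint IgG is returned as a function of the candidate MoA map.
#'
#' @param spec population spec for the cohort.
#' @param schedule trial schedule.
#' @param n patients per arm.
#' @param masterSeed cohort master seed.
#' @param C0 reference serum concentration (ng/ml).
#' @param config engine configuration.
#' @param chemical chemical id for the exposure profiles.
#' @return \code{function(moa) -> percent effect}.
#' @export
trialEffectFn <- function(spec, schedule, n, masterSeed, C0,
                          config = defaultConfig(), chemical = "PFOA") {
  cohort <- generateCohort(n, spec, masterSeed)
  ps <- spec@poolScale
  function(moa) {
    ref <- runTrial(cohort, schedule, constantExposure(C0, chemical),
                    config, moa, poolScale = ps)
    x2 <- runTrial(cohort, schedule, constantExposure(2 * C0, chemical),
                   config, moa, poolScale = ps)
    foldChangeEffect(ref@endpoints$endpoint_IgG,
                     x2@endpoints$endpoint_IgG)$effect
  }
}

#' Calibrate the shared Imax against a fold-change effect target
#'
#' Bisection on the shared maximal suppression \code{Imax} in [0, 1] until
#' the effect computed by \code{effectFn} (the simulated percent difference
#' per 2-fold exposure, negative for suppression) is within \code{tol}
#' percentage points of \code{targetEffect}. The response must be monotone
#' non-increasing in \code{Imax}; a target more negative than the effect at
#' \code{Imax = 1} is unreachable and reported as such.
#'
#' @param targetEffect target percent difference (<= 0).
#' @param effectFn function mapping a \code{\link{MoAMap}} to the measured
#'   effect (see \code{\link{trialEffectFn}}).
#' @param moa template map whose shared Imax is tuned.
#' @param tol tolerance in percentage points.
#' @param maxIter maximum bisection iterations.
#' @return List: \code{moa} (calibrated map), \code{Imax}, \code{achieved}
#'   (measured effect at the returned Imax), \code{converged},
#'   \code{trace} (data.frame of iterates).
#' @export
calibrateMoa <- function(targetEffect, effectFn, moa = defaultMoAMap(),
                         tol = 3, maxIter = 12L) {
  if (targetEffect > 0) stop("targetEffect must be <= 0", call. = FALSE)
  trace <- data.frame(Imax = numeric(0), effect = numeric(0))
  if (targetEffect == 0) {
    m0 <- setSharedImax(moa, 0)
    return(list(moa = m0, Imax = 0, achieved = 0, converged = TRUE,
                trace = trace))
  }
  eval1 <- function(i) {
    eff <- effectFn(setSharedImax(moa, i))
    trace <<- rbind(trace, data.frame(Imax = i, effect = eff))
    eff
  }
  hiEff <- eval1(1)
  # far beyond the Imax = 1 asymptote: report unreachable rather than search
  if (hiEff > targetEffect + 10 * tol) {
    return(list(moa = setSharedImax(moa, 1), Imax = 1, achieved = hiEff,
                converged = FALSE, trace = trace))
  }
  lo <- 0; hi <- 1
  mid <- 0.5; eff <- NA_real_
  for (k in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    eff <- eval1(mid)
    if (abs(eff - targetEffect) <= tol) break
    if (eff > targetEffect) lo <- mid else hi <- mid
  }
  list(moa = setSharedImax(moa, mid), Imax = mid, achieved = eff,
       converged = abs(eff - targetEffect) <= tol, trace = trace)
}

#' Mean-endpoint reduction function over constant exposure
#'
#' Builds the closure used by \code{\link{benchmarkDose}}: the percent
#' reduction of the cohort-mean endpoint IgG at constant serum concentration
#' \code{C} relative to the paired unexposed run (computed once).
#'
#' @inheritParams trialEffectFn
#' @param moa mechanism-of-action map (typically the calibrated default).
#' @return \code{function(C) -> percent reduction} (positive = suppression).
#' @export
trialReductionFn <- function(spec, schedule, n, masterSeed,
                             config = defaultConfig(), moa = defaultMoAMap(),
                             chemical = "PFOA") {
  cohort <- generateCohort(n, spec, masterSeed)
  ps <- spec@poolScale
  base <- runTrial(cohort, schedule, NULL, config, moa, poolScale = ps)
  m0 <- mean(base@endpoints$endpoint_IgG)
  function(C) {
    if (C == 0) return(0)
    r <- runTrial(cohort, schedule, constantExposure(C, chemical),
                  config, moa, poolScale = ps)
    100 * (1 - mean(r@endpoints$endpoint_IgG) / m0)
  }
}

#' Benchmark dose for a predetermined antibody-response reduction
#'
#' Bisection on the constant serum concentration until the percent reduction
#' in the mean antibody endpoint (paired against the unexposed run) is within
#' \code{tol} of \code{targetReduction}. The search assumes a monotone
#' exposure-response; the bracket grows geometrically until the target is
#' enclosed (up to \code{Cmax}).
#'
#' @param targetReduction target percent reduction in (0, 100).
#' @param reductionFn function \code{C -> percent reduction} (see
#'   \code{\link{trialReductionFn}}).
#' @param tol tolerance in percentage points.
#' @param Cmax upper search bound (ng/ml).
#' @param maxIter maximum bisection iterations.
#' @return List: \code{bmd} (ng/ml), \code{achieved}, \code{converged},
#'   \code{trace}.
#' @export
benchmarkDose <- function(targetReduction, reductionFn, tol = 0.5,
                          Cmax = 1e4, maxIter = 40L) {
  if (targetReduction <= 0) {
    if (targetReduction == 0)
      return(list(bmd = 0, achieved = 0, converged = TRUE,
                  trace = data.frame(C = 0, reduction = 0)))
    stop("targetReduction must be in (0, 100)", call. = FALSE)
  }
  trace <- data.frame(C = numeric(0), reduction = numeric(0))
  evalC <- function(C) {
    r <- reductionFn(C)
    trace <<- rbind(trace, data.frame(C = C, reduction = r))
    r
  }
  hi <- 1
  rHi <- evalC(hi)
  while (rHi < targetReduction && hi < Cmax) {
    hi <- hi * 4
    rHi <- evalC(hi)
  }
  if (rHi < targetReduction)
    return(list(bmd = NA_real_, achieved = rHi, converged = FALSE,
                trace = trace))
  lo <- 0
  mid <- hi / 2; r <- NA_real_
  for (k in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    r <- evalC(mid)
    if (abs(r - targetReduction) <= tol) break
    if (r < targetReduction) lo <- mid else hi <- mid
  }
  list(bmd = mid, achieved = r, converged = abs(r - targetReduction) <= tol,
       trace = trace)
}
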