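# Chemical exposure and mechanism-of-action layer. Serum concentration is an
# exogenous step-constant time course (no ADME/kinetics). Each mechanism-of-
# action entry suppresses one engine rate through a Hill/Emax factor
#   f(C) = 1 - Imax * C^h / (C^h + EC50^h),
# continuous and non-increasing in C with range [1 - Imax, 1]. The shipped
# PFOA/PFOS map targets secretion of IL-6, TNF-alpha, IL-4, IL-8, IL-18,
# IFN-gamma and IL-10, the spleen B-cell homeostatic mean, thymic output, and
# mast-cell growth; PFOS differs from PFOA only by a potency multiplier on C.

#' Serum-concentration exposure profile
#'
#' Step-constant time course of the serum concentration of one chemical, in
#' ng/ml; the concentration is 0 before the first defined time point.
#'
#' @slot chemical character id (e.g. \code{"PFOA"}, \code{"PFOS"}).
#' @slot times integer steps at which the concentration changes (sorted).
#' @slot conc concentrations (ng/ml) applying from each time point on.
#' @export
setClass("ExposureProfile",
  representation(chemical = "character", times = "numeric", conc = "numeric"))

setValidity("ExposureProfile", function(object) {
  msg <- character()
  if (length(object@times) != length(object@conc))
    msg <- c(msg, "times and conc must have equal length")
  if (is.unsorted(object@times, strictly = TRUE) && length(object@times) > 1L)
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@conc < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param chemical chemical id.
#' @param times change-point steps.
#' @param conc concentrations from each change point on (ng/ml).
#' @rdname ExposureProfile-class
#' @examples
#' ep <- ExposureProfile("PFOA", times = 0, conc = 10)
#' serumConcentration(ep, 50)  # 10
#' @export
ExposureProfile <- function(chemical = "PFOA", times = 0, conc = 0) {
  o <- order(times)
  new("ExposureProfile", chemical = chemical,
      times = as.numeric(times[o]), conc = as.numeric(conc[o]))
}

#' A constant exposure from step 0
#' @param conc constant serum concentration (ng/ml).
#' @param chemical chemical id.
#' @export
constantExposure <- function(conc, chemical = "PFOA")
  ExposureProfile(chemical, times = 0, conc = conc)

setMethod("show", "ExposureProfile", function(object) {
  cat(sprintf("ExposureProfile '%s': %d change point(s), range %.3g-%.3g ng/ml\n",
              object@chemical, length(object@times),
              min(c(object@conc, 0)), max(c(object@conc, 0))))
})

#' Serum concentration at a time step
#'
#' Step-constant lookup: the concentration defined by the latest change point
#' at or before \code{t}, and 0 before the first change point.
#'
#' @param profile an \code{\link{ExposureProfile}}.
#' @param t step (>= 0); vectorized.
#' @return Concentration(s) in ng/ml.
#' @rdname serumConcentration
#' @export
setMethod("serumConcentration", signature(profile = "ExposureProfile", t = "numeric"),
  function(profile, t) {
    if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
    if (length(profile@times) == 0L) return(rep(0, length(t)))
    i <- findInterval(t, profile@times)
    ifelse(i == 0L, 0, profile@conc[pmax(i, 1L)])
  })

#' Hill-type suppression factor
#'
#' Multiplier applied to a targeted engine rate at serum concentration
#' \code{C}: \code{1 - Imax * C^hill / (C^hill + EC50^hill)}. Equals 1 at
#' \code{C = 0}, decreases continuously with \code{C} and tends to
#' \code{1 - Imax} as \code{C} grows.
#'
#' @param C serum concentration, ng/ml (>= 0); vectorized.
#' @param Imax maximal fractional suppression in [0, 1].
#' @param EC50 half-maximal concentration, ng/ml (> 0).
#' @param hill Hill coefficient (> 0).
#' @return Factor(s) in \code{[1 - Imax, 1]}.
#' @export
suppressionFactor <- function(C, Imax, EC50, hill = 1) {
  if (any(C < 0)) stop("C must be >= 0", call. = FALSE)
  if (Imax < 0 || Imax > 1) stop("Imax must be in [0, 1]", call. = FALSE)
  if (EC50 <= 0) stop("EC50 must be > 0", call. = FALSE)
  if (hill <= 0) stop("hill must be > 0", call. = FALSE)
  ch <- C^hill
  1 - Imax * ch / (ch + EC50^hill)
}

#' Mechanism-of-action map for a chemical class
#'
#' The list of engine rates a chemical suppresses, with per-target Hill
#' parameters. Targets are \code{CYTOKINE_SECRETION} (one entry per species),
#' \code{B_POOL_MU} (spleen B-cell homeostatic mean), \code{THYMIC_OUTPUT}
#' (thymic emigration rate) and \code{MAST_GROWTH}. All entries are
#' suppressive (factor <= 1). Several chemicals may share one map with
#' per-chemical potency multipliers on the serum concentration.
#'
#' @slot entries data.frame with columns \code{target}, \code{species}
#'   (NA unless target is CYTOKINE_SECRETION), \code{Imax}, \code{EC50},
#'   \code{hill}.
#' @slot potency named numeric: per-chemical multiplier applied to C.
#' @export
setClass("MoAMap",
  representation(entries = "data.frame", potency = "numeric"))

.moaTargets <- c("CYTOKINE_SECRETION", "B_POOL_MU", "THYMIC_OUTPUT", "MAST_GROWTH")

setValidity("MoAMap", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("target", "species", "Imax", "EC50", "hill")
  if (!all(need %in% names(e))) return("entries must have columns target, species, Imax, EC50, hill")
  if (!all(e$target %in% .moaTargets)) msg <- c(msg, "unknown target")
  if (any(e$Imax < 0 | e$Imax > 1)) msg <- c(msg, "Imax must be in [0, 1]")
  if (any(e$EC50 <= 0)) msg <- c(msg, "EC50 must be > 0")
  if (any(e$hill <= 0)) msg <- c(msg, "hill must be > 0")
  bad <- e$target == "CYTOKINE_SECRETION" & !e$species %in% cytokineSpecies()
  if (any(bad)) msg <- c(msg, "CYTOKINE_SECRETION entries need a known species")
  if (is.null(names(object@potency)) || any(object@potency <= 0))
    msg <- c(msg, "potency must be a named positive numeric vector")
  if (length(msg)) msg else TRUE
})

#' @param entries data.frame of MoA entries (see slots).
#' @param potency named per-chemical potency multipliers.
#' @rdname MoAMap-class
#' @export
MoAMap <- function(entries, potency = c(PFOA = 1, PFOS = 1.5)) {
  entries$target <- as.character(entries$target)
  entries$species <- as.character(entries$species)
  new("MoAMap", entries = entries, potency = potency)
}

setMethod("show", "MoAMap", function(object) {
  cat(sprintf("MoAMap: %d entries (%d cytokine targets), chemicals: %s\n",
              nrow(object@entries),
              sum(object@entries$target == "CYTOKINE_SECRETION"),
              paste(names(object@potency), collapse = ", ")))
})

#' The shipped PFOA/PFOS mechanism-of-action map
#'
#' Reads the default calibrated map from the package's parameter file:
#' suppression of IL-6, TNF-alpha, IL-4, IL-8, IL-18, IFN-gamma and IL-10
#' secretion, of the B-cell homeostatic mean, of thymic output and of
#' mast-cell growth. The shared Imax is the value produced by the shipped
#' calibration script against the 2-fold exposure effect on the diphtheria
#' antibody endpoint; relative magnitudes across the seven cytokines are
#' equal because no quantitative ordering is published.
#'
#' @return A \code{\link{MoAMap}}.
#' @export
defaultMoAMap <- function() {
  path <- system.file("extdata", "moa_pfas.yaml", package = "immunotox")
  readMoAMap(path)
}

#' Read a mechanism-of-action map from YAML
#' @param path YAML file with fields \code{potency} and \code{entries}.
#' @export
readMoAMap <- function(path) {
  y <- yaml::read_yaml(path)
  e <- do.call(rbind, lapply(y$entries, function(r)
    data.frame(target = r$target,
               species = if (is.null(r$species)) NA_character_ else r$species,
               Imax = r$Imax, EC50 = r$EC50, hill = r$hill,
               stringsAsFactors = FALSE)))
  MoAMap(e, potency = unlist(y$potency))
}

#' Rate multipliers implied by an exposure at one step
#'
#' Evaluates every entry of the chemical's mechanism-of-action map at the
#' current serum concentration (scaled by the chemical's potency) and returns
#' the multipliers the engine applies: one per targeted cytokine species, and
#' one each for the B-pool homeostatic mean, thymic output and mast-cell
#' growth. Untargeted rates keep multiplier 1; with \code{C = 0} every
#' multiplier is exactly 1.
#'
#' @param profile an \code{\link{ExposureProfile}}.
#' @param moa a \code{\link{MoAMap}} containing the profile's chemical.
#' @param t current step.
#' @return List with \code{cytokine} (named numeric over all species),
#'   \code{bPoolMu}, \code{thymicOutput}, \code{mastGrowth}.
#' @export
applyExposure <- function(profile, moa, t) {
  chem <- profile@chemical
  if (!chem %in% names(moa@potency))
    stop(sprintf("chemical '%s' not in MoA map", chem), call. = FALSE)
  C <- serumConcentration(profile, t) * moa@potency[[chem]]
  cyt <- setNames(rep(1, length(cytokineSpecies())), cytokineSpecies())
  out <- list(cytokine = cyt, bPoolMu = 1, thymicOutput = 1, mastGrowth = 1)
  e <- moa@entries
  for (i in seq_len(nrow(e))) {
    f <- suppressionFactor(C, e$Imax[i], e$EC50[i], e$hill[i])
    switch(e$target[i],
      CYTOKINE_SECRETION = { out$cytokine[[e$species[i]]] <- out$cytokine[[e$species[i]]] * f },
      B_POOL_MU = { out$bPoolMu <- out$bPoolMu * f },
      THYMIC_OUTPUT = { out$thymicOutput <- out$thymicOutput * f },
      MAST_GROWTH = { out$mastGrowth <- out$mastGrowth * f })
  }
  out
}
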