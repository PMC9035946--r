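# Virtual-patient synthesis. A patient is the 26-field personalization
# vector (exposure, cell pools, baseline cytokines, specific IgG titre, age,
# BMI, disease-model / vaccination / mechanism-of-action references) plus HLA
# class I and II haplotype pairs and a private seed. Marginals are truncated
# normals with dependency-aware conditional means (e.g. BMI given age, naive
# pools declining with age); sampling is rejection-based within bounds.
#
# Table rows 10 and 20 both carry the IL-10 baseline; the schema keeps both
# entries (aliased to one value) to preserve the printed 26-entry count, and
# row 1 is one exposure field accepting either PFOA or PFOS as chemical id.

.featureOrder <- c("PFOA", "Th1", "Th2", "M", "DC", "IgG", "TC", "IL1",
                   "IL2", "IL10", "IL12", "IL17A", "IL23", "IFN1A", "IFN1B",
                   "IFNG", "TNF", "VitaminD", "Treg", "IL10_r20", "TGFB",
                   "Age", "BMI", "DiseaseModel", "VC", "MoA")
.categoricalFeatures <- c("DiseaseModel", "VC", "MoA")

#' The 26-entry virtual-patient feature schema
#'
#' Feature names in table order. \code{IL10} appears twice in the printed
#' vector (rows 10 and 20); the second entry is kept as \code{IL10_r20} and
#' aliased to the same underlying value.
#' @export
patientFeatureNames <- function() .featureOrder

#' Population specification for virtual-patient synthesis
#'
#' @slot features data.frame of numeric marginals: \code{name}, \code{mean},
#'   \code{sd}, \code{lower}, \code{upper}, \code{dependsOn} (NA or a feature
#'   name), \code{slope} (conditional mean shift per unit of the parent,
#'   centred at the parent's marginal mean).
#' @slot categorical named list of fixed categorical entries.
#' @slot hlaPool integer vector of haplotype bit strings.
#' @slot poolScale scale factor applied to lineage pools at engine
#'   initialization (e.g. < 1 for children).
#' @slot label character.
#' @export
setClass("PopulationSpec",
  representation(features = "data.frame", categorical = "list",
                 hlaPool = "integer", poolScale = "numeric",
                 label = "character"))

setValidity("PopulationSpec", function(object) {
  f <- object@features
  msg <- character()
  numeric_needed <- setdiff(setdiff(.featureOrder, .categoricalFeatures), "IL10_r20")
  if (!all(numeric_needed %in% f$name))
    msg <- c(msg, "every numeric schema feature needs a marginal")
  if (!all(.categoricalFeatures %in% names(object@categorical)))
    msg <- c(msg, "categorical entries DiseaseModel, VC, MoA required")
  if (any(f$sd < 0)) msg <- c(msg, "sd must be >= 0")
  if (any(f$lower > f$upper)) msg <- c(msg, "lower must be <= upper")
  dep <- f$dependsOn[!is.na(f$dependsOn)]
  if (!all(dep %in% f$name)) msg <- c(msg, "dependency on unknown feature")
  if (length(object@hlaPool) == 0L) msg <- c(msg, "hlaPool must be non-empty")
  if (length(msg)) msg else TRUE
})

.marginal <- function(name, mean, sd, lower, upper,
                      dependsOn = NA_character_, slope = 0)
  data.frame(name = name, mean = mean, sd = sd, lower = lower, upper = upper,
             dependsOn = dependsOn, slope = slope, stringsAsFactors = FALSE)

#' Adult population specification
#'
#' Healthy adults aged 18-60 with typical-value/standard-deviation truncated
#' normal marginals, BMI conditionally dependent on age, and naive T pools
#' declining with age (waning thymic output). Serum exposure is a skewed
#' positive marginal in ng/ml.
#'
#' @param hlaPool haplotype pool; defaults to the configured synthetic pool.
#' @export
adultPopulationSpec <- function(hlaPool = defaultConfig()$hlaPool) {
  f <- rbind(
    .marginal("PFOA", 4, 2.5, 0.1, 30),
    .marginal("Th1", 60, 10, 20, 120, "Age", -0.25),
    .marginal("Th2", 60, 10, 20, 120, "Age", -0.25),
    .marginal("M", 30, 6, 10, 60),
    .marginal("DC", 30, 6, 10, 60),
    .marginal("IgG", 10, 3, 0, 30),
    .marginal("TC", 60, 10, 20, 120, "Age", -0.3),
    .marginal("IL1", 0.5, 0.15, 0, 2),
    .marginal("IL2", 0.5, 0.15, 0, 2),
    .marginal("IL10", 0.5, 0.15, 0, 2),
    .marginal("IL12", 0.5, 0.15, 0, 2),
    .marginal("IL17A", 0.5, 0.15, 0, 2),
    .marginal("IL23", 0.5, 0.15, 0, 2),
    .marginal("IFN1A", 0.5, 0.15, 0, 2),
    .marginal("IFN1B", 0.5, 0.15, 0, 2),
    .marginal("IFNG", 0.5, 0.15, 0, 2),
    .marginal("TNF", 0.5, 0.15, 0, 2),
    .marginal("VitaminD", 30, 8, 5, 80),
    .marginal("Treg", 20, 5, 5, 50),
    .marginal("TGFB", 0.5, 0.15, 0, 2),
    .marginal("Age", 39, 12, 18, 60),
    .marginal("BMI", 24, 3, 16, 45, "Age", 0.08))
  new("PopulationSpec", features = f,
      categorical = list(DiseaseModel = "generic-bacterial", VC = "none",
                         MoA = "PFAS-default"),
      hlaPool = as.integer(hlaPool), poolScale = 1.0, label = "adult")
}

#' Child population specification
#'
#' Children around 5 years of age; lineage pools scaled by a documented
#' factor relative to the adult engine defaults, child-range BMI.
#' @param hlaPool haplotype pool.
#' @export
childPopulationSpec <- function(hlaPool = defaultConfig()$hlaPool) {
  spec <- adultPopulationSpec(hlaPool)
  f <- spec@features
  f[f$name == "Age", c("mean", "sd", "lower", "upper", "slope")] <-
    list(5, 0.5, 4, 6, 0)
  f[f$name == "BMI", c("mean", "sd", "lower", "upper", "slope")] <-
    list(15.5, 1.5, 12, 25, 0)
  for (nm in c("Th1", "Th2", "TC")) {
    f[f$name == nm, c("dependsOn", "slope")] <- list(NA_character_, 0)
  }
  initialize(spec, features = f, poolScale = 0.85, label = "child",
             categorical = list(DiseaseModel = "generic-bacterial",
                                VC = "diphtheria", MoA = "PFAS-default"))
}

#' A fully personalized virtual patient
#'
#' @slot features named numeric vector over the numeric schema entries
#'   (including the aliased \code{IL10_r20}).
#' @slot categorical named list: DiseaseModel, VC, MoA.
#' @slot hlaI,hlaII HLA haplotype pairs (bit strings).
#' @slot seed private integer seed driving this patient's simulations.
#' @slot specLabel label of the generating population spec.
#' @export
setClass("VirtualPatient",
  representation(features = "numeric", categorical = "list",
                 hlaI = "integer", hlaII = "integer", seed = "integer",
                 specLabel = "character"))

setMethod("show", "VirtualPatient", function(object) {
  cat(sprintf("VirtualPatient (%s): age %.1f, exposure %.2f ng/ml, seed %d\n",
              object@specLabel, object@features[["Age"]],
              object@features[["PFOA"]], object@seed))
})

#' Draw HLA haplotypes uniformly from the allele pool
#'
#' Both class I and class II haplotype pairs are drawn uniformly with
#' replacement from the configured pool of (synthetic) allele bit strings.
#'
#' @param pool non-empty integer vector of haplotype bit strings.
#' @return List with \code{hlaI} and \code{hlaII}, each of length 2.
#' @export
sampleHLA <- function(pool) {
  if (length(pool) == 0L) stop("HLA pool is empty", call. = FALSE)
  list(hlaI = as.integer(pool[sample.int(length(pool), 2L, replace = TRUE)]),
       hlaII = as.integer(pool[sample.int(length(pool), 2L, replace = TRUE)]))
}

.sampleTruncNorm <- function(mean, sd, lower, upper, maxTries = 100L) {
  if (sd == 0) {
    v <- min(max(mean, lower), upper)
    return(v)
  }
  for (i in seq_len(maxTries)) {
    v <- rnorm(1L, mean, sd)
    if (v >= lower && v <= upper) return(v)
  }
  stop("unsatisfiable bounds after 100 attempts", call. = FALSE)
}

#' Sample one virtual patient
#'
#' Numeric features are drawn in dependency order: parents first, then
#' children with conditional means shifted by \code{slope * (parent -
#' parentMean)}. Bound violations are rejection-resampled (at most 100
#' attempts per feature). Uses the current RNG stream.
#'
#' @param spec a \code{\link{PopulationSpec}}.
#' @return A \code{\link{VirtualPatient}}.
#' @export
samplePatient <- function(spec) {
  f <- spec@features
  vals <- setNames(rep(NA_real_, nrow(f)), f$name)
  roots <- f$name[is.na(f$dependsOn)]
  for (nm in roots) {
    r <- f[f$name == nm, ]
    vals[[nm]] <- .sampleTruncNorm(r$mean, r$sd, r$lower, r$upper)
  }
  pending <- f$name[!is.na(f$dependsOn)]
  while (length(pending)) {
    ready <- pending[vapply(pending, function(nm)
      !is.na(vals[[f$dependsOn[f$name == nm]]]), TRUE)]
    if (!length(ready)) stop("cyclic dependency in population spec", call. = FALSE)
    for (nm in ready) {
      r <- f[f$name == nm, ]
      parent <- r$dependsOn
      pmean <- f$mean[f$name == parent]
      mu <- r$mean + r$slope * (vals[[parent]] - pmean)
      vals[[nm]] <- .sampleTruncNorm(mu, r$sd, r$lower, r$upper)
    }
    pending <- setdiff(pending, ready)
  }
  vals <- c(vals, IL10_r20 = unname(vals[["IL10"]]))
  hla <- sampleHLA(spec@hlaPool)
  new("VirtualPatient",
      features = vals[setdiff(.featureOrder, .categoricalFeatures)],
      categorical = spec@categorical,
      hlaI = hla$hlaI, hlaII = hla$hlaII,
      seed = sample.int(.Machine$integer.max, 1L),
      specLabel = spec@label)
}

#' Validate a virtual patient against a population spec
#'
#' Returns an empty data.frame when every invariant holds; otherwise one row
#' per violation naming the feature, its value and the violated bound.
#'
#' @param patient a \code{\link{VirtualPatient}}.
#' @param spec the \code{\link{PopulationSpec}} to validate against.
#' @rdname validatePatient
#' @export
setMethod("validatePatient",
  signature(patient = "VirtualPatient", spec = "PopulationSpec"),
  function(patient, spec) {
    v <- data.frame(feature = character(), value = numeric(),
                    bound = character(), stringsAsFactors = FALSE)
    numNames <- setdiff(.featureOrder, .categoricalFeatures)
    missing <- setdiff(numNames, names(patient@features))
    for (nm in missing)
      v <- rbind(v, data.frame(feature = nm, value = NA_real_,
                               bound = "missing from schema"))
    f <- spec@features
    for (i in seq_len(nrow(f))) {
      nm <- f$name[i]
      if (!nm %in% names(patient@features)) next
      x <- patient@features[[nm]]
      if (x < f$lower[i])
        v <- rbind(v, data.frame(feature = nm, value = x,
                                 bound = sprintf(">= %g", f$lower[i])))
      if (x > f$upper[i])
        v <- rbind(v, data.frame(feature = nm, value = x,
                                 bound = sprintf("<= %g", f$upper[i])))
    }
    if (all(c("IL10", "IL10_r20") %in% names(patient@features)) &&
        patient@features[["IL10"]] != patient@features[["IL10_r20"]])
      v <- rbind(v, data.frame(feature = "IL10_r20",
                               value = patient@features[["IL10_r20"]],
                               bound = "alias of IL10"))
    for (nm in .categoricalFeatures)
      if (is.null(patient@categorical[[nm]]))
        v <- rbind(v, data.frame(feature = nm, value = NA_real_,
                                 bound = "missing from schema"))
    v
  })

#' A reproducible cohort of virtual patients
#'
#' @slot patients list of \code{\link{VirtualPatient}}.
#' @slot masterSeed the seed the per-patient seeds were split from.
#' @slot label population label.
#' @export
setClass("PatientCohort",
  representation(patients = "list", masterSeed = "integer", label = "character"))

setMethod("show", "PatientCohort", function(object) {
  cat(sprintf("PatientCohort '%s': %d patients (master seed %d)\n",
              object@label, length(object@patients), object@masterSeed))
})

#' Generate a cohort of virtual patients
#'
#' Seed splitting: the master seed seeds one draw of \code{n} independent
#' 31-bit patient seeds; each patient is then sampled under its own seed, so
#' patients are mutually independent and the whole cohort is byte-identical
#' across runs with the same master seed. Two cohorts generated from the same
#' master seed share patient seeds (common random numbers for paired-arm
#' contrasts).
#'
#' @param n cohort size (>= 0).
#' @param spec a \code{\link{PopulationSpec}}.
#' @param masterSeed integer master seed.
#' @return A \code{\link{PatientCohort}}.
#' @export
generateCohort <- function(n, spec, masterSeed) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be >= 0", call. = FALSE)
  set.seed(masterSeed)
  seeds <- sample.int(.Machine$integer.max, max(n, 1L))
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    p <- samplePatient(spec)
    p@seed <- seeds[i]
    patients[[i]] <- p
  }
  new("PatientCohort", patients = patients,
      masterSeed = as.integer(masterSeed), label = spec@label)
}

#' Cohort as a delimited-ready table
#'
#' One row per patient, one column per schema feature (categoricals
#' included), plus the HLA haplotypes and the patient seed.
#' @param cohort a \code{\link{PatientCohort}}.
#' @export
cohortTable <- function(cohort) {
  rows <- lapply(seq_along(cohort@patients), function(i) {
    p <- cohort@patients[[i]]
    num <- as.list(p@features)
    cat_ <- p@categorical[.categoricalFeatures]
    df <- data.frame(patient_id = i, c(num, cat_), stringsAsFactors = FALSE)
    df$hlaI_1 <- p@hlaI[1]; df$hlaI_2 <- p@hlaI[2]
    df$hlaII_1 <- p@hlaII[1]; df$hlaII_2 <- p@hlaII[2]
    df$seed <- p@seed
    df
  })
  do.call(rbind, rows)
}
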