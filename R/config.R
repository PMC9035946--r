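# Global configuration. All engine rates, thresholds, lattice settings,
# lineage pools and the antigen catalogue ship in a versioned YAML parameter
# file under inst/extdata; defaultConfig() reads it and userland overrides
# merge on top. None of the per-type half-lives, secretion rates or initial
# counts are published for the original platform; the shipped values are
# order-of-magnitude modelling choices, documented in the methods vignette.

.cfgCache <- new.env(parent = emptyenv())

#' The shipped default configuration
#'
#' Reads \code{inst/extdata/default_params.yaml}: bit-string length and
#' affinity parameters, lattice geometry, time step (8 simulated hours, 3
#' steps per day), interaction probabilities, thymic-selection thresholds,
#' Ornstein-Uhlenbeck homeostasis parameters, lineage pools, half-lives,
#' division/differentiation rates, the secretion table and the antigen
#' catalogue.
#'
#' @param overrides optional named list merged over the defaults (one level
#'   deep per component).
#' @return A configuration list.
#' @export
defaultConfig <- function(overrides = NULL) {
  if (is.null(.cfgCache$cfg)) {
    path <- system.file("extdata", "default_params.yaml", package = "immunotox")
    .cfgCache$cfg <- .parseConfig(yaml::read_yaml(path))
  }
  cfg <- .cfgCache$cfg
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Read a configuration file
#' @param path a YAML file with the same structure as the shipped defaults.
#' @export
readConfig <- function(path) .parseConfig(yaml::read_yaml(path))

.parseConfig <- function(y) {
  y$secretion <- do.call(rbind, lapply(y$secretion, function(r)
    data.frame(type = r$type, state = r$state, species = r$species,
               rate = r$rate, stringsAsFactors = FALSE)))
  y$hlaPool <- as.integer(y$hlaPool)
  y$l <- as.integer(y$l)
  y
}

#' Steps per simulated day
#' @param cfg a configuration list.
#' @export
stepsPerDay <- function(cfg = defaultConfig()) as.integer(cfg$stepsPerDay)

#' Convert days to steps under the configured time step
#' @param day day number(s).
#' @param cfg a configuration list.
#' @export
dayToStep <- function(day, cfg = defaultConfig()) as.integer(round(day * cfg$stepsPerDay))

#' Antigen definition from the configured catalogue
#' @param id antigen id (e.g. \code{"diphtheria"}, \code{"bacteria"}).
#' @param cfg a configuration list.
#' @return List with \code{epitope}, \code{peptides}, \code{pamp}, \code{dose}.
#' @export
antigenDef <- function(id, cfg = defaultConfig()) {
  a <- cfg$antigens[[id]]
  if (is.null(a)) stop(sprintf("unknown antigen '%s'", id), call. = FALSE)
  list(epitope = as.integer(a$epitope), peptides = as.integer(unlist(a$peptides)),
       pamp = isTRUE(a$pamp), dose = as.integer(a$dose))
}
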