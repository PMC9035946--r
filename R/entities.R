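# Cellular and molecular entity catalogue. Cell agents carry a type, lattice
# position, internal state, receptor (lymphocytes only), age, half-life and a
# duplication counter bounded by the Hayflick limit. Internally the engine
# holds agents as parallel integer vectors (a column store) for speed; the
# helpers here define the catalogue and the per-agent primitives.

#' Cell types recognised by the simulator
#' @export
cellTypes <- function() c("B", "PLB", "TH1", "TH2", "TC", "TREG", "NK",
                          "MONO", "MAC", "DC", "MAST", "NEU")

#' Internal states a cell agent can occupy
#' @export
cellStates <- function() c("RESTING", "ACTIVE", "PRESENTING_II", "PRESENTING_I",
                           "DUPLICATING", "ANERGIC", "MEMORY")

#' Tracked cytokine species
#'
#' The fifteen interleukin/interferon/TNF species carried as per-site
#' molecular fields: the cytokine rows of the virtual-patient feature vector
#' plus IL-4, IL-6, IL-8 and IL-18, which the PFAS mechanism-of-action map
#' targets.
#' @export
cytokineSpecies <- function() c("IL1", "IL2", "IL4", "IL6", "IL8", "IL10",
                                "IL12", "IL17", "IL18", "IL23", "IFNG",
                                "IFNA1", "IFNB1", "TNFA", "TGFB")

#' Immunoglobulin isotypes
#' @export
igIsotypes <- function() c("IgM", "IgG", "IgA")

#' Anatomical compartments
#' @export
compartments <- function() c("BONE_MARROW", "THYMUS", "SECONDARY_ORGAN")

#' Per-type state-transition table
#'
#' The allowed states and transitions per cell type, as used by the engine.
#' Every transition the engine performs appears here; the table is data, so
#' rule extensions do not touch engine code.
#'
#' @return A named list: per type, a list with \code{states} (allowed set) and
#'   \code{transitions} (two-column matrix \code{from -> to}).
#' @export
transitionTable <- function() {
  tr <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE,
                             dimnames = list(NULL, c("from", "to")))
  list(
    B = list(
      states = c("RESTING", "ACTIVE", "PRESENTING_II", "DUPLICATING",
                 "ANERGIC", "MEMORY"),
      transitions = tr("RESTING", "ACTIVE",
                       "MEMORY", "ACTIVE",
                       "MEMORY", "DUPLICATING",
                       "ACTIVE", "PRESENTING_II",
                       "PRESENTING_II", "DUPLICATING",
                       "PRESENTING_II", "ANERGIC",
                       "DUPLICATING", "DUPLICATING",
                       "DUPLICATING", "MEMORY")),
    PLB = list(states = "ACTIVE", transitions = tr("ACTIVE", "ACTIVE")),
    TH1 = list(
      states = c("RESTING", "ACTIVE", "ANERGIC", "MEMORY"),
      transitions = tr("RESTING", "ACTIVE", "MEMORY", "ACTIVE",
                       "ACTIVE", "RESTING", "ACTIVE", "MEMORY")),
    TH2 = list(
      states = c("RESTING", "ACTIVE", "ANERGIC", "MEMORY"),
      transitions = tr("RESTING", "ACTIVE", "MEMORY", "ACTIVE",
                       "ACTIVE", "RESTING", "ACTIVE", "MEMORY")),
    TC = list(
      states = c("RESTING", "ACTIVE", "ANERGIC", "MEMORY"),
      transitions = tr("RESTING", "ACTIVE", "ACTIVE", "RESTING",
                       "ACTIVE", "MEMORY")),
    TREG = list(states = "RESTING", transitions = tr("RESTING", "RESTING")),
    NK = list(states = "RESTING", transitions = tr("RESTING", "RESTING")),
    MONO = list(
      states = c("RESTING", "ACTIVE", "PRESENTING_II", "PRESENTING_I"),
      transitions = tr("RESTING", "PRESENTING_II", "RESTING", "PRESENTING_I",
                       "PRESENTING_II", "RESTING", "PRESENTING_I", "RESTING")),
    MAC = list(
      states = c("RESTING", "ACTIVE", "PRESENTING_II", "PRESENTING_I"),
      transitions = tr("RESTING", "PRESENTING_II", "RESTING", "PRESENTING_I",
                       "PRESENTING_II", "RESTING", "PRESENTING_I", "RESTING")),
    DC = list(
      states = c("RESTING", "ACTIVE", "PRESENTING_II", "PRESENTING_I"),
      transitions = tr("RESTING", "PRESENTING_II", "RESTING", "PRESENTING_I",
                       "PRESENTING_II", "RESTING", "PRESENTING_I", "RESTING")),
    MAST = list(states = "RESTING", transitions = tr("RESTING", "RESTING")),
    NEU = list(states = "RESTING", transitions = tr("RESTING", "RESTING"))
  )
}

#' Geometric survival: one lifecycle step
#'
#' Survival is memoryless, parameterized by the half-life: each step an agent
#' is removed with probability \code{1 - 2^(-1/halfLife)}, so half of a cohort
#' survives \code{halfLife} steps in expectation.
#'
#' @param halfLife half-life in steps (> 0); vectorized over agents.
#' @return Logical vector, \code{TRUE} where the agent survives the step.
#' @examples
#' set.seed(1)
#' mean(stepLifecycle(rep(10, 1e4)))  # ~ 2^(-1/10)
#' @export
stepLifecycle <- function(halfLife) {
  if (length(halfLife) == 0L) return(logical(0))
  if (any(halfLife <= 0)) stop("halfLife must be > 0", call. = FALSE)
  runif(length(halfLife)) < 2^(-1 / halfLife)
}

#' Per-step removal probability implied by a half-life
#' @param halfLife half-life in steps.
#' @export
removalProbability <- function(halfLife) 1 - 2^(-1 / halfLife)

#' IL-4 driven isotype switching
#'
#' At activation, an IgM B/plasma cell switches to IgG when the local IL-4
#' concentration reaches the threshold. Switching is monotone: IgG and IgA
#' never revert to IgM.
#'
#' @param isotype current isotype(s), one of \code{"IgM"}, \code{"IgG"},
#'   \code{"IgA"}.
#' @param il4 local IL-4 concentration(s).
#' @param threshold switching threshold (same units as \code{il4}).
#' @param cellType cell type of the agent(s); must be \code{"B"} or
#'   \code{"PLB"}.
#' @return Updated isotype vector.
#' @export
isotypeSwitch <- function(isotype, il4, threshold, cellType = "B") {
  if (!all(cellType %in% c("B", "PLB")))
    stop("isotype switching applies to B and PLB cells only", call. = FALSE)
  if (!all(isotype %in% igIsotypes())) stop("unknown isotype", call. = FALSE)
  ifelse(isotype == "IgM" & il4 >= threshold, "IgG", isotype)
}

# ---- internal agent column store -------------------------------------------

# codes used in the engine's integer columns
.typeCode  <- function(x) match(x, cellTypes())
.stateCode <- function(x) match(x, cellStates())
.isoCode   <- function(x) match(x, igIsotypes())
.compCode  <- function(x) match(x, compartments())

.emptyAgents <- function() {
  list(type = integer(0), state = integer(0), pos = integer(0),
       receptor = integer(0), age = integer(0), halfLife = numeric(0),
       dup = integer(0), isotype = integer(0), comp = integer(0),
       complex = integer(0), wait = integer(0), uid = numeric(0))
}

.nAgents <- function(a) length(a$type)

.makeAgents <- function(n, type, pos, receptor = NA_integer_,
                        halfLife, comp = "SECONDARY_ORGAN",
                        state = "RESTING", isotype = NA_integer_,
                        uid = NA_real_) {
  list(type = rep(.typeCode(type), length.out = n),
       state = rep(.stateCode(state), length.out = n),
       pos = rep(as.integer(pos), length.out = n),
       receptor = rep(as.integer(receptor), length.out = n),
       age = integer(n),
       halfLife = rep(as.numeric(halfLife), length.out = n),
       dup = integer(n),
       isotype = rep(as.integer(isotype), length.out = n),
       comp = rep(.compCode(comp), length.out = n),
       complex = rep(NA_integer_, n),
       wait = integer(n),
       uid = rep(as.numeric(uid), length.out = n))
}

.bindAgents <- function(a, b) {
  if (.nAgents(b) == 0L) return(a)
  if (.nAgents(a) == 0L) return(b)
  mapply(c, a, b, SIMPLIFY = FALSE)
}

.subsetAgents <- function(a, keep) lapply(a, `[`, keep)
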