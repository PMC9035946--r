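# The simulation loop. Each world step applies, in a fixed documented order:
#   exposure update -> haematopoiesis -> thymic education/emigration ->
#   per-site randomized interactions -> maturation & clonal expansion ->
#   secretion -> field diffusion/decay -> agent diffusion -> lifecycle.
# All interactions couple entities at one lattice site only, through a
# per-site randomized Bernoulli schedule: interaction rules are permuted,
# actor lists are permuted within each rule, and every actor gets at most one
# success per rule. The whole run is a pure function of (config, seed).

#' Ornstein-Uhlenbeck parameters for one haematopoietic lineage
#'
#' @slot mu target (homeostatic) cell count.
#' @slot theta mean-reversion rate per step (> 0).
#' @slot sigma noise scale per step (>= 0).
#' @export
setClass("OUParams",
  representation(mu = "numeric", theta = "numeric", sigma = "numeric"))

setValidity("OUParams", function(object) {
  msg <- character()
  if (object@theta <= 0) msg <- c(msg, "theta must be > 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param mu,theta,sigma see slots.
#' @rdname OUParams-class
#' @export
OUParams <- function(mu, theta = 0.1, sigma = 1)
  new("OUParams", mu = as.numeric(mu), theta = as.numeric(theta),
      sigma = as.numeric(sigma))

#' One step of the mean-reverting haematopoiesis process
#'
#' Exact discretization of the Ornstein-Uhlenbeck process over \code{dt}:
#' \deqn{x' = \mu + (x-\mu)e^{-\theta dt} +
#'       \sigma\sqrt{(1-e^{-2\theta dt})/(2\theta)}\,\epsilon,}
#' with standard-normal \eqn{\epsilon}. By default the result is clamped at 0
#' and rounded to an integer cell count; \code{round = FALSE} returns the raw
#' real-valued update (the closed form used by the homeostasis tests).
#'
#' @param x current count.
#' @param params an \code{\link{OUParams}}.
#' @param dt time increment in steps.
#' @param round clamp/round to an integer count?
#' @return Updated count.
#' @export
ouStep <- function(x, params, dt = 1, round = TRUE) {
  stopifnot(is(params, "OUParams"))
  e <- exp(-params@theta * dt)
  sdv <- params@sigma * sqrt((1 - exp(-2 * params@theta * dt)) / (2 * params@theta))
  xp <- params@mu + (x - params@mu) * e + sdv * rnorm(length(x))
  if (round) pmax(0, round(xp)) else xp
}

# ---- thymic education ------------------------------------------------------

#' Positive thymic selection
#'
#' A maturing T cell is kept only if its receptor shows at least minimal
#' affinity to some MHC string of the appropriate class: keep iff the maximum
#' Hamming distance (complementarity) to any MHC string reaches
#' \code{thetaPos}.
#'
#' @param receptor receptor bit string(s); vectorized.
#' @param mhcSet non-empty integer vector of MHC bit strings.
#' @param thetaPos minimum complementary bits for survival.
#' @param l string length in bits.
#' @return Logical vector, \code{TRUE} = keep.
#' @export
thymusPositive <- function(receptor, mhcSet, thetaPos, l) {
  if (length(mhcSet) == 0L) stop("mhcSet must be non-empty", call. = FALSE)
  best <- rep(-1L, length(receptor))
  for (m in mhcSet) best <- pmax(best, hammingDistance(receptor, m, l))
  best >= thetaPos
}

#' Negative thymic selection
#'
#' A T cell is deleted if its receptor has high affinity to any
#' MHC--self-peptide complex: remove iff the maximum complementarity to a
#' self complex reaches \code{thetaNeg}. An empty self set keeps everything.
#'
#' @param receptor receptor bit string(s); vectorized.
#' @param selfComplexes integer vector of MHC-self-peptide complex strings.
#' @param thetaNeg complementary bits above which the cell is autoreactive.
#' @param l string length in bits.
#' @return Logical vector, \code{TRUE} = keep.
#' @export
thymusNegative <- function(receptor, selfComplexes, thetaNeg, l) {
  if (length(selfComplexes) == 0L) return(rep(TRUE, length(receptor)))
  best <- rep(-1L, length(receptor))
  for (m in selfComplexes) best <- pmax(best, hammingDistance(receptor, m, l))
  best < thetaNeg
}

#' Two-stage thymic education
#'
#' Positive selection against the MHC set, then negative selection against
#' the MHC--self-peptide complexes, in that order. Survivors satisfy both
#' predicates.
#'
#' @param repertoire integer vector of receptor bit strings.
#' @param mhcSet MHC strings for the positive stage.
#' @param selfComplexes self complexes for the negative stage.
#' @param thetaPos,thetaNeg selection thresholds, \code{0 <= thetaPos <=
#'   thetaNeg <= l + 1}.
#' @param l string length in bits.
#' @return The surviving receptors (subset of \code{repertoire}).
#' @export
thymusEducation <- function(repertoire, mhcSet, selfComplexes,
                            thetaPos, thetaNeg, l) {
  if (thetaPos < 0 || thetaNeg < thetaPos)
    stop("need 0 <= thetaPos <= thetaNeg", call. = FALSE)
  if (length(repertoire) == 0L) return(integer(0))
  keep <- thymusPositive(repertoire, mhcSet, thetaPos, l)
  r2 <- repertoire[keep]
  r2[thymusNegative(r2, selfComplexes, thetaNeg, l)]
}

# ---- antigen processing and presentation -----------------------------------

#' MHC--peptide complex string
#'
#' Deterministic, length-preserving combiner: the bitwise XOR of the MHC and
#' peptide strings.
#' @param mhc,peptide bit strings.
#' @export
mhcComplex <- function(mhc, peptide) bitwXor(as.integer(mhc), as.integer(peptide))

#' Antigen processing and presentation
#'
#' Tests every peptide of the antigen against every MHC string of the
#' pathway's class (endocytic pathway -> class II, cytosolic -> class I) in
#' deterministic order; each pair binds with \code{\link{bindingProbability}}.
#' On the first success the presenting cell carries the MHC--peptide complex
#' (bitwise XOR).
#'
#' @param peptides integer vector of antigen peptide strings (>= 1).
#' @param mhcI,mhcII the cell's MHC haplotype pairs (integer vectors).
#' @param pathway \code{"ENDOCYTIC"} or \code{"CYTOSOLIC"}.
#' @param params an \code{\link{AffinityParams}}.
#' @return The complex string on success, or \code{NA_integer_}.
#' @export
processAndPresent <- function(peptides, mhcI, mhcII,
                              pathway = c("ENDOCYTIC", "CYTOSOLIC"), params) {
  pathway <- match.arg(pathway)
  mhc <- if (pathway == "ENDOCYTIC") mhcII else mhcI
  if (length(mhc) == 0L)
    stop("presenting cell lacks MHC of the pathway's class", call. = FALSE)
  if (length(peptides) == 0L) stop("antigen must carry >= 1 peptide", call. = FALSE)
  for (m in mhc) for (p in peptides) {
    if (runif(1) < bindingProbability(m, p, params))
      return(mhcComplex(m, p))
  }
  NA_integer_
}

# count of (mhc, peptide) pairs that can bind at all (p > 0); brute-force aid
#' Number of presentable MHC--peptide pairs
#' @param peptides,mhc integer bit-string vectors.
#' @param params an \code{\link{AffinityParams}}.
#' @export
presentablePairs <- function(peptides, mhc, params) {
  n <- 0L
  for (m in mhc) n <- n + sum(bindingProbability(m, peptides, params) > 0)
  n
}

# ---- clonal expansion ------------------------------------------------------

#' Clonal expansion bookkeeping
#'
#' A cell in the duplicating state divides into two daughters with
#' duplication counter \code{parent + 1}, unless the parent has reached the
#' Hayflick limit, in which case no division occurs. Receptor inheritance
#' (and any hypermutation of B-cell daughters) is applied by the caller.
#'
#' @param dup parent duplication count(s); vectorized.
#' @param hayflick the Hayflick limit on divisions.
#' @return Integer vector: number of daughters (0 or 2) per parent.
#' @export
clonalExpansion <- function(dup, hayflick) {
  ifelse(dup >= hayflick, 0L, 2L)
}

# ---- per-site randomized interaction scheduling ----------------------------

#' Build the randomized per-site interaction schedule
#'
#' Permutes the interaction rules uniformly, and within each rule permutes the
#' list of candidate actors uniformly. Deterministic under a fixed RNG seed.
#'
#' @param rules list of interaction rules; each rule is a list with at least
#'   an \code{actors} vector (ids of type-A entities at the site).
#' @return List with \code{ruleOrder} (permutation of rule indices) and
#'   \code{actorOrders} (per rule, a permutation of its actor list).
#' @export
buildSiteSchedule <- function(rules) {
  nr <- length(rules)
  ruleOrder <- if (nr > 1L) sample.int(nr) else seq_len(nr)
  actorOrders <- lapply(rules, function(r) {
    na <- length(r$actors)
    if (na > 1L) sample.int(na) else seq_len(na)
  })
  list(ruleOrder = ruleOrder, actorOrders = actorOrders)
}

#' Execute the interactions of one lattice site
#'
#' Runs the randomized schedule: for each rule (in random order), each actor
#' (in random order) is compared with the rule's partners until a successful
#' interaction occurs; every actor--partner attempt is an independent
#' Bernoulli draw. Each actor achieves at most one success per rule, and
#' partners consumed by a consuming rule are unavailable to all later
#' attempts (within and across rules, matched by entity id).
#'
#' @param rules list of rules; each rule is a list with fields:
#'   \describe{
#'     \item{name}{character label.}
#'     \item{actors}{vector of actor entity ids.}
#'     \item{partners}{vector of partner entity ids.}
#'     \item{prob}{either a single probability (aspecific rule) or a matrix
#'       \code{[length(actors) x length(partners)]} of per-pair probabilities
#'       (specific rule, typically from \code{\link{bindingProbability}}).}
#'     \item{consumes}{logical: does a success consume the partner?}
#'   }
#' @return data.frame with one interaction event per row: \code{rule},
#'   \code{actor}, \code{partner}.
#' @export
executeSiteInteractions <- function(rules) {
  sched <- buildSiteSchedule(rules)
  consumed <- character(0)
  evRule <- character(0); evA <- numeric(0); evB <- numeric(0)
  for (ri in sched$ruleOrder) {
    rule <- rules[[ri]]
    if (length(rule$actors) == 0L || length(rule$partners) == 0L) next
    actors <- rule$actors[sched$actorOrders[[ri]]]
    pm <- rule$prob
    for (ai in seq_along(actors)) {
      a <- actors[ai]
      if (as.character(a) %in% consumed) next
      ok <- !(as.character(rule$partners) %in% consumed) & rule$partners != a
      if (!any(ok)) next
      bIdx <- which(ok)
      pv <- if (is.matrix(pm)) {
        row <- which(rule$actors == a)[1L]
        pm[row, bIdx]
      } else rep(pm, length(bIdx))
      hit <- which(runif(length(bIdx)) < pv)
      if (length(hit)) {
        b <- rule$partners[bIdx[hit[1L]]]
        evRule <- c(evRule, rule$name); evA <- c(evA, a); evB <- c(evB, b)
        if (isTRUE(rule$consumes)) consumed <- c(consumed, as.character(b))
      }
    }
  }
  data.frame(rule = evRule, actor = evA, partner = evB,
             stringsAsFactors = FALSE)
}

# ---- engine state ----------------------------------------------------------

# The world state is an environment with: cfg, lat, ap/apMem (AffinityParams),
# agents (column store), cyt (species x sites matrix), antigens (list with
# unit position vectors), ig (clonotype table + bulk), hlaI/hlaII,
# selfComplexes, mult (current tox multipliers), ouX (per-lineage OU state),
# clock, initialized.

.unitMult <- function() {
  list(cytokine = setNames(rep(1, length(cytokineSpecies())), cytokineSpecies()),
       bPoolMu = 1, thymicOutput = 1, mastGrowth = 1)
}

.lineages <- c("B", "TH1", "TH2", "TC", "TREG", "NK", "MONO", "MAC", "DC",
               "MAST", "NEU")
.tLineages <- c("TH1", "TH2", "TC")

#' Initialize the world state
#'
#' Builds the three-compartment world and fills it to the lineage homeostatic
#' means with naive cells (T cells are thymus-educated before placement), sets
#' cytokine fields to their baseline totals spread uniformly over the lattice,
#' and seeds the immunoglobulin pool with the baseline bulk IgG titre. Uses
#' the current RNG stream; seed externally for reproducibility.
#'
#' @param cfg a configuration list from \code{\link{defaultConfig}}.
#' @param hlaI,hlaII MHC haplotype pairs (integer bit strings); defaults are
#'   drawn from the configured pool.
#' @param pools optional named overrides of the lineage homeostatic means.
#' @param baselines optional named cytokine baseline totals (model units).
#' @param igG0 baseline bulk IgG titre.
#' @return The state environment.
#' @export
initState <- function(cfg, hlaI = NULL, hlaII = NULL, pools = NULL,
                      baselines = NULL, igG0 = 0) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$lat <- Lattice(cfg$lattice$geometry, cfg$lattice$side, cfg$lattice$boundary)
  st$ap <- AffinityParams(cfg$l, cfg$affinity$dMin, cfg$affinity$alpha,
                          cfg$affinity$pMax)
  st$apMem <- AffinityParams(cfg$l, max(0L, cfg$affinity$dMin - cfg$memoryRelax),
                             cfg$affinity$alpha, cfg$affinity$pMax)
  st$apMHC <- AffinityParams(cfg$l, cfg$mhcAffinity$dMin, cfg$mhcAffinity$alpha,
                             cfg$mhcAffinity$pMax)
  ns <- nSites(st$lat)
  pool <- cfg$hlaPool
  if (is.null(hlaI)) hlaI <- pool[sample.int(length(pool), 2L, replace = TRUE)]
  if (is.null(hlaII)) hlaII <- pool[sample.int(length(pool), 2L, replace = TRUE)]
  st$hlaI <- as.integer(hlaI); st$hlaII <- as.integer(hlaII)
  selfPep <- sampleRepertoire(cfg$thymus$nSelf, cfg$l)
  st$selfComplexes <- as.integer(outer(c(st$hlaI, st$hlaII), selfPep, mhcComplex))

  mus <- unlist(cfg$pools)[.lineages]
  if (!is.null(pools)) mus[names(pools)] <- unlist(pools)
  st$mu <- mus
  st$ouX <- round(mus)

  ag <- .emptyAgents()
  st$created <- setNames(integer(length(.lineages)), .lineages)
  for (lin in .lineages) {
    n <- as.integer(round(mus[[lin]]))
    if (n == 0L) next
    hl <- .lineageHalfLife(cfg, lin)
    if (lin %in% .tLineages) {
      rec <- .educatedReceptors(st, lin, n)
    } else if (lin == "B") {
      rec <- sampleRepertoire(n, cfg$l)
    } else rec <- rep(NA_integer_, n)
    iso <- if (lin == "B") .isoCode("IgM") else NA_integer_
    linId <- match(lin, .lineages)
    a <- .makeAgents(n, lin, pos = sample.int(ns, n, replace = TRUE) - 1L,
                     receptor = rec, halfLife = hl, isotype = iso,
                     uid = linId * 1e9 + seq_len(n))
    st$created[[lin]] <- n
    ag <- .bindAgents(ag, a)
  }
  st$agents <- ag

  base <- cfg$cytBaseline
  if (!is.null(baselines)) base[names(baselines)] <- unlist(baselines)
  st$cyt <- matrix(unlist(base[cytokineSpecies()]) / ns,
                   nrow = length(cytokineSpecies()), ncol = ns,
                   dimnames = list(cytokineSpecies(), NULL))
  st$antigens <- list()
  st$ig <- list(paratope = integer(0), isotype = integer(0), conc = numeric(0),
                bulk = c(IgM = 0, IgG = igG0, IgA = 0))
  st$mult <- .unitMult()
  st$clock <- 0L
  st$seedBase <- NA_integer_
  st$antCreated <- list()
  st$initialized <- TRUE
  st
}

#' Enable per-phase common-random-number streams
#'
#' Derives one RNG substream per (step, phase) from a base seed, so that two
#' runs of the same patient under different exposures share identical noise
#' everywhere the exposure does not change an outcome (common random numbers:
#' paired contrasts then differ only through the exposure effect, and
#' responses vary smoothly in the suppression parameters). Without a base
#' seed the engine consumes one global RNG stream.
#'
#' @param st the state environment.
#' @param seed integer base seed (typically the patient's seed).
#' @export
useCrnStreams <- function(st, seed) {
  st$seedBase <- as.integer(seed)
  invisible(st)
}

.phaseSeed <- function(st, phase) {
  if (is.na(st$seedBase)) return(invisible(NULL))
  set.seed((st$seedBase %% 90000L) * 21000L + st$clock * 16L + phase)
  invisible(NULL)
}

# Quasi-random uniform draws keyed by persistent entity identity. Under
# common random numbers every (entity, step, purpose) triple maps to one
# fixed uniform deviate, so paired runs share identical noise and differ
# only where the exposure flips an outcome; without a base seed the draws
# fall back to the global RNG stream.
.crnU <- function(st, uid, salt) {
  if (is.na(st$seedBase)) return(runif(length(uid)))
  x <- sin((uid %% 99991) * 12.9898 + st$clock * 78.2330 +
             salt * 37.7190 + (st$seedBase %% 10007) * 0.6180339) * 43758.5453
  x - floor(x)
}

# clock-independent variant for one-off draws keyed by a creation counter
.crnK <- function(st, key, salt) {
  if (is.na(st$seedBase)) return(runif(length(key)))
  x <- sin((key %% 99991) * 12.9898 + salt * 37.7190 +
             (st$seedBase %% 10007) * 0.6180339) * 43758.5453
  x - floor(x)
}

.lineageHalfLife <- function(cfg, lin) {
  hl <- cfg$halfLife
  switch(lin, PLB = hl$plb, B = hl$naive, TH1 = hl$naive, TH2 = hl$naive,
         TC = hl$naive, hl$innate)
}

# sample receptors, push through thymic education, repeat until n survivors
.educatedReceptors <- function(st, lin, n) {
  cfg <- st$cfg
  mhcSet <- if (lin == "TC") st$hlaI else st$hlaII
  out <- integer(0)
  tries <- 0L
  while (length(out) < n && tries < 50L) {
    cand <- sampleRepertoire(max(2L * n, 32L), cfg$l)
    out <- c(out, thymusEducation(cand, mhcSet, st$selfComplexes,
                                  cfg$thymus$thetaPos, cfg$thymus$thetaNeg,
                                  cfg$l))
    tries <- tries + 1L
  }
  out[seq_len(n)]
}

#' Inject an antigen bolus into the secondary organ
#'
#' Distributes \code{dose} antigen units uniformly at random over the lattice
#' sites of the secondary-organ compartment (challenges and vaccine doses are
#' always injected there).
#'
#' @param st the state environment.
#' @param name antigen id.
#' @param epitope B-epitope bit string.
#' @param peptides peptide bit strings (>= 1).
#' @param pamp does the antigen carry a PAMP (TLR-recognized) signature?
#' @param dose number of units.
#' @export
injectAntigen <- function(st, name, epitope, peptides, pamp, dose) {
  ns <- nSites(st$lat)
  cnt <- if (is.null(st$antCreated[[name]])) 0L else st$antCreated[[name]]
  nameKey <- (sum(utf8ToInt(name)) %% 887) * 1e7
  uid <- nameKey + cnt + seq_len(dose)
  st$antCreated[[name]] <- cnt + dose
  pos <- if (is.na(st$seedBase)) sample.int(ns, dose, replace = TRUE) - 1L
         else as.integer(floor(.crnK(st, uid, 17) * ns))
  if (is.null(st$antigens[[name]])) {
    st$antigens[[name]] <- list(epitope = as.integer(epitope),
                                peptides = as.integer(peptides),
                                pamp = isTRUE(pamp), pos = pos, uid = uid)
  } else {
    st$antigens[[name]]$pos <- c(st$antigens[[name]]$pos, pos)
    st$antigens[[name]]$uid <- c(st$antigens[[name]]$uid, uid)
  }
  invisible(st)
}

#' Antigen-specific immunoglobulin titre
#'
#' Sums the serum clonotype pool over the paratopes able to bind the
#' antigen's B epitope (complementarity at or above the binding threshold).
#'
#' @param st the state environment.
#' @param epitope the antigen's B-epitope bit string.
#' @param isotype one of \code{"IgM"}, \code{"IgG"}, \code{"IgA"}.
#' @return Total specific titre (model units).
#' @export
specificTiter <- function(st, epitope, isotype = "IgG") {
  ig <- st$ig
  if (length(ig$paratope) == 0L) return(0)
  sel <- ig$isotype == .isoCode(isotype) &
    hammingDistance(ig$paratope, epitope, st$cfg$l) >= st$ap@dMin
  sum(ig$conc[sel])
}

# ---- world step ------------------------------------------------------------

#' Advance the world by one time step
#'
#' Applies the phases in the frozen order documented at the top of the
#' engine: exposure update, haematopoiesis, thymic education and emigration,
#' per-site randomized interactions, maturation and clonal expansion,
#' secretion, field diffusion and decay, agent diffusion, lifecycle. Advances
#' the clock by one step (8 simulated hours by default). Bit-identical under
#' a fixed seed.
#'
#' @param st the state environment from \code{\link{initState}}.
#' @param exposure an \code{\link{ExposureProfile}} or \code{NULL}.
#' @param moa a \code{\link{MoAMap}} (required when \code{exposure} given).
#' @return The state, invisibly.
#' @export
stepWorld <- function(st, exposure = NULL, moa = NULL) {
  if (!isTRUE(st$initialized)) stop("state is not initialized", call. = FALSE)
  cfg <- st$cfg
  st$mult <- if (is.null(exposure)) .unitMult()
             else applyExposure(exposure, moa, st$clock)
  .phaseSeed(st, 1L); .phaseHaematopoiesis(st)
  .phaseSeed(st, 2L); .phaseThymus(st)
  .phaseSeed(st, 3L); .phaseInteractions(st)
  .phaseSeed(st, 4L); .phaseMaturation(st)
  .phaseSeed(st, 5L); .phaseSecretion(st)
  .phaseSeed(st, 6L); .phaseFields(st)
  .phaseSeed(st, 7L); .phaseAgentDiffusion(st)
  .phaseSeed(st, 8L); .phaseLifecycle(st)
  st$clock <- st$clock + 1L
  invisible(st)
}

.phaseHaematopoiesis <- function(st) {
  cfg <- st$cfg
  ag <- st$agents
  ns <- nSites(st$lat)
  naive <- ag$state == .stateCode("RESTING") & ag$dup == 0L &
    ag$comp == .compCode("SECONDARY_ORGAN")
  newA <- .emptyAgents()
  drop <- logical(.nAgents(ag))
  # all OU updates first: a fixed number of draws per step keeps paired
  # (common-random-number) runs aligned however many cells each arm creates
  for (lin in .lineages) {
    mu <- st$mu[[lin]]
    if (lin == "B") mu <- mu * st$mult$bPoolMu
    op <- OUParams(mu, cfg$ou$theta, cfg$ou$sigma)
    st$ouX[[lin]] <- ouStep(st$ouX[[lin]], op)
  }
  for (lin in .lineages) {
    cur <- sum(naive & ag$type == .typeCode(lin)) +
      if (lin %in% .tLineages)
        sum(ag$type == .typeCode(lin) & ag$comp == .compCode("THYMUS")) else 0L
    deficit <- st$ouX[[lin]] - cur
    if (deficit > 0L) {
      hl <- .lineageHalfLife(cfg, lin)
      draws <- .creationDraws(st, lin, deficit, ns)
      if (lin %in% .tLineages) {
        a <- .makeAgents(deficit, lin, pos = draws$pos,
                         receptor = draws$rec,
                         halfLife = hl, comp = "THYMUS", uid = draws$uid)
      } else {
        rec <- if (lin == "B") draws$rec else NA_integer_
        iso <- if (lin == "B") .isoCode("IgM") else NA_integer_
        a <- .makeAgents(deficit, lin, pos = draws$pos,
                         receptor = rec, halfLife = hl, isotype = iso,
                         uid = draws$uid)
      }
      newA <- .bindAgents(newA, a)
    } else if (deficit < 0L) {
      cand <- which(naive & ag$type == .typeCode(lin))
      if (length(cand)) {
        old <- cand[order(-ag$age[cand])]
        drop[head(old, min(length(old), -deficit))] <- TRUE
      }
    }
  }
  if (any(drop)) ag <- .subsetAgents(ag, !drop)
  st$agents <- .bindAgents(ag, newA)
  invisible(st)
}

# receptor/position draws for newly created cells, keyed by the lineage's
# cumulative creation counter: under common random numbers, paired runs see
# the same receptor sequence per lineage regardless of how many cells each
# arm creates, so the responding repertoires stay aligned across arms
.creationDraws <- function(st, lin, n, ns) {
  linId <- match(lin, .lineages)
  k <- st$created[[lin]] + seq_len(n)
  st$created[[lin]] <- st$created[[lin]] + n
  uid <- linId * 1e9 + k
  if (is.na(st$seedBase)) {
    return(list(rec = sampleRepertoire(n, st$cfg$l),
                pos = sample.int(ns, n, replace = TRUE) - 1L, uid = uid))
  }
  key <- k * 13 + linId
  rec <- as.integer(floor(.crnK(st, key, 13) * 2^st$cfg$l))
  pos <- as.integer(floor(.crnK(st, key, 14) * ns))
  list(rec = rec, pos = pos, uid = uid)
}

.phaseThymus <- function(st) {
  cfg <- st$cfg
  ag <- st$agents
  inThy <- which(ag$comp == .compCode("THYMUS"))
  if (!length(inThy)) return(invisible(st))
  keep <- rep(TRUE, .nAgents(ag))
  ns <- nSites(st$lat)
  for (lin in .tLineages) {
    idx <- inThy[ag$type[inThy] == .typeCode(lin)]
    if (!length(idx)) next
    mhcSet <- if (lin == "TC") st$hlaI else st$hlaII
    rec <- ag$receptor[idx]
    ok <- thymusPositive(rec, mhcSet, cfg$thymus$thetaPos, cfg$l) &
      thymusNegative(rec, st$selfComplexes, cfg$thymus$thetaNeg, cfg$l)
    keep[idx[!ok]] <- FALSE
    surv <- idx[ok]
    if (length(surv)) {
      emig <- .crnU(st, ag$uid[surv], 12) <
        cfg$thymus$emigration * st$mult$thymicOutput
      out <- surv[emig]
      ag$comp[out] <- .compCode("SECONDARY_ORGAN")
      ag$pos[out] <- sample.int(ns, length(out), replace = TRUE) - 1L
    }
  }
  st$agents <- .subsetAgents(ag, keep)
  invisible(st)
}

# per-site interactions: builds local rule contexts and runs the randomized
# schedule at each site where something can happen.
.phaseInteractions <- function(st) {
  cfg <- st$cfg
  ag <- st$agents
  n <- .nAgents(ag)
  sec <- ag$comp == .compCode("SECONDARY_ORGAN")
  ns <- nSites(st$lat)

  antNames <- names(st$antigens)
  antCounts <- lapply(st$antigens, function(a) tabulate(a$pos + 1L, ns))
  anyAnt <- length(antNames) && any(vapply(antCounts, sum, 0) > 0)

  presII <- sec & ag$state == .stateCode("PRESENTING_II")
  presI  <- sec & ag$state == .stateCode("PRESENTING_I")
  thAct  <- sec & ag$state == .stateCode("ACTIVE") &
    ag$type %in% .typeCode(c("TH1", "TH2"))
  bPres  <- presII & ag$type == .typeCode("B")

  activeSites <- logical(ns)
  if (anyAnt) for (ac in antCounts) activeSites <- activeSites | ac > 0L
  activeSites[ag$pos[presII | presI] + 1L] <- TRUE
  sites <- which(activeSites) - 1L
  if (!length(sites)) return(invisible(st))

  # site -> agent index map for agents in the secondary organ
  secIdx <- which(sec)
  bySite <- split(secIdx, ag$pos[secIdx])

  apcT <- .typeCode(c("MONO", "MAC", "DC"))
  consumedAnt <- lapply(antCounts, function(x) integer(0))
  names(consumedAnt) <- antNames

  for (s in sites) {
    # one CRN substream per (step, site): an exposure-induced event flip
    # stays local to its site instead of shifting every later draw
    if (!is.na(st$seedBase))
      set.seed((st$seedBase %% 50021L) * 40000L + st$clock * 600L + s)
    loc <- bySite[[as.character(s)]]
    if (is.null(loc)) loc <- integer(0)
    lt <- ag$type[loc]; lstate <- ag$state[loc]
    rules <- list()
    # ids: agents use 1..nLoc (site-local); antigen units use k*100000 + u
    if (length(antNames)) for (k in seq_along(antNames)) {
      m <- antCounts[[k]][s + 1L]
      if (m == 0L) next
      adef <- st$antigens[[antNames[k]]]
      unitIds <- k * 100000 + seq_len(m)
      apc <- which(lt %in% apcT & lstate == .stateCode("RESTING"))
      if (length(apc)) {
        rules[[length(rules) + 1L]] <- list(
          name = paste0("uptake:", antNames[k]),
          actors = loc[apc], partners = unitIds,
          prob = if (adef$pamp) cfg$pAspecific else cfg$pNonPamp,
          consumes = TRUE)
      }
      bcells <- which(lt == .typeCode("B") &
                        lstate %in% .stateCode(c("RESTING", "MEMORY")))
      if (length(bcells)) {
        bi <- loc[bcells]
        mem <- ag$state[bi] == .stateCode("MEMORY")
        pv <- numeric(length(bi))
        pv[!mem] <- bindingProbability(ag$receptor[bi[!mem]], adef$epitope, st$ap)
        pv[mem] <- bindingProbability(ag$receptor[bi[mem]], adef$epitope, st$apMem)
        rules[[length(rules) + 1L]] <- list(
          name = paste0("bcapture:", antNames[k]),
          actors = bi, partners = unitIds,
          prob = matrix(pv, nrow = length(bi), ncol = m),
          consumes = TRUE)
      }
    }
    prII <- loc[ag$state[loc] == .stateCode("PRESENTING_II")]
    if (length(prII)) {
      th <- loc[lt %in% .typeCode(c("TH1", "TH2")) &
                  lstate %in% .stateCode(c("RESTING", "MEMORY"))]
      if (length(th)) {
        pm <- outer(ag$receptor[th], ag$complex[prII],
                    function(a, b) bindingProbability(a, b, st$ap))
        rules[[length(rules) + 1L]] <- list(
          name = "th_prime", actors = th, partners = prII, prob = pm,
          consumes = FALSE)
      }
      bp <- prII[ag$type[prII] == .typeCode("B")]
      thA <- loc[lt %in% .typeCode(c("TH1", "TH2")) &
                   lstate == .stateCode("ACTIVE")]
      if (length(bp) && length(thA)) {
        pm <- outer(seq_along(bp), seq_along(thA), function(i, j)
          bindingProbability(ag$receptor[thA[j]], ag$complex[bp[i]], st$ap))
        rules[[length(rules) + 1L]] <- list(
          name = "b_help", actors = bp, partners = thA, prob = pm,
          consumes = FALSE)
      }
    }
    prI <- loc[ag$state[loc] == .stateCode("PRESENTING_I")]
    if (length(prI)) {
      tc <- loc[lt == .typeCode("TC") & lstate == .stateCode("RESTING")]
      if (length(tc)) {
        pm <- outer(ag$receptor[tc], ag$complex[prI],
                    function(a, b) bindingProbability(a, b, st$ap))
        rules[[length(rules) + 1L]] <- list(
          name = "tc_prime", actors = tc, partners = prI, prob = pm,
          consumes = FALSE)
      }
    }
    if (!length(rules)) next
    ev <- executeSiteInteractions(rules)
    if (!nrow(ev)) next
    for (i in seq_len(nrow(ev))) {
      rn <- ev$rule[i]
      if (startsWith(rn, "uptake:")) {
        aname <- sub("^uptake:", "", rn)
        adef <- st$antigens[[aname]]
        gi <- ev$actor[i]
        # cytosolic cross-presentation attempted when the endocytic route fails
        cx <- processAndPresent(adef$peptides, st$hlaI, st$hlaII,
                                "ENDOCYTIC", st$apMHC)
        if (!is.na(cx)) {
          ag$state[gi] <- .stateCode("PRESENTING_II"); ag$complex[gi] <- cx
        } else {
          cx <- processAndPresent(adef$peptides, st$hlaI, st$hlaII,
                                  "CYTOSOLIC", st$apMHC)
          if (!is.na(cx)) {
            ag$state[gi] <- .stateCode("PRESENTING_I"); ag$complex[gi] <- cx
          }
        }
        k <- match(aname, antNames)
        consumedAnt[[k]] <- c(consumedAnt[[k]], s)
      } else if (startsWith(rn, "bcapture:")) {
        aname <- sub("^bcapture:", "", rn)
        adef <- st$antigens[[aname]]
        gi <- ev$actor[i]
        if (ag$state[gi] == .stateCode("MEMORY")) {
          ag$state[gi] <- .stateCode("DUPLICATING")
          ag$dup[gi] <- 0L
        } else {
          ag$state[gi] <- .stateCode("ACTIVE")
        }
        ag$complex[gi] <- mhcComplex(st$hlaII[1L], adef$peptides[1L])
        ag$wait[gi] <- 0L
        k <- match(aname, antNames)
        consumedAnt[[k]] <- c(consumedAnt[[k]], s)
      } else if (rn == "th_prime") {
        ag$state[ev$actor[i]] <- .stateCode("ACTIVE")
      } else if (rn == "b_help") {
        ag$state[ev$actor[i]] <- .stateCode("DUPLICATING")
        ag$wait[ev$actor[i]] <- 0L
      } else if (rn == "tc_prime") {
        ag$state[ev$actor[i]] <- .stateCode("ACTIVE")
      }
    }
  }
  # remove consumed antigen units (one unit per consumption event, at its site)
  for (k in seq_along(antNames)) {
    cs <- consumedAnt[[k]]
    if (!length(cs)) next
    adef <- st$antigens[[antNames[k]]]
    keep <- rep(TRUE, length(adef$pos))
    for (s in cs) {
      hit <- which(adef$pos == s & keep)
      if (length(hit)) keep[hit[1L]] <- FALSE
    }
    st$antigens[[antNames[k]]]$pos <- adef$pos[keep]
    st$antigens[[antNames[k]]]$uid <- adef$uid[keep]
  }
  st$agents <- ag
  invisible(st)
}

.phaseMaturation <- function(st) {
  cfg <- st$cfg
  ag <- st$agents
  ns <- nSites(st$lat)
  il4site <- st$cyt["IL4", ]

  # B ACTIVE (captured antigen) -> PRESENTING_II next step
  bAct <- which(ag$type == .typeCode("B") & ag$state == .stateCode("ACTIVE"))
  ag$state[bAct] <- .stateCode("PRESENTING_II")

  # anergy: a presenting B with no co-stimulatory APC at its site for longer
  # than the anergy window becomes unresponsive
  bPres <- which(ag$type == .typeCode("B") &
                   ag$state == .stateCode("PRESENTING_II"))
  if (length(bPres)) {
    ag$wait[bPres] <- ag$wait[bPres] + 1L
    apcBusy <- ag$type %in% .typeCode(c("MONO", "MAC", "DC")) &
      ag$state %in% .stateCode(c("ACTIVE", "PRESENTING_II", "PRESENTING_I"))
    apcAt <- tabulate(ag$pos[apcBusy] + 1L, ns)
    anergic <- bPres[ag$wait[bPres] > cfg$anergyWindow &
                       apcAt[ag$pos[bPres] + 1L] == 0L]
    ag$state[anergic] <- .stateCode("ANERGIC")
  }

  # clonal expansion of duplicating B cells; daughter identities derive from
  # the parent identity so paired runs share clone trees
  bDup <- which(ag$type == .typeCode("B") &
                  ag$state == .stateCode("DUPLICATING"))
  if (length(bDup) && .nAgents(ag) < cfg$maxAgents) {
    div <- bDup[.crnU(st, ag$uid[bDup], 20) < cfg$division$pDiv]
    div <- div[clonalExpansion(ag$dup[div], cfg$hayflick) > 0L]
    if (length(div)) {
      nd <- length(div)
      dl <- list()
      for (j in 1:2) {
        uidJ <- (ag$uid[div] * 4 + j) %% 9e15
        recJ <- ag$receptor[div]
        hm <- which(.crnU(st, uidJ, 21) < cfg$division$pHyper)
        if (length(hm)) {
          bit <- floor(.crnU(st, uidJ[hm], 22) * cfg$l)
          recJ[hm] <- bitwXor(recJ[hm], bitwShiftL(1L, as.integer(bit)))
        }
        u <- .crnU(st, uidJ, 23)
        fate <- ifelse(u < cfg$division$fPLB, "PLB",
                       ifelse(u < cfg$division$fPLB + cfg$division$fMem,
                              "MEM", "DUP"))
        for (f in c("PLB", "MEM", "DUP")) {
          ii <- which(fate == f)
          if (!length(ii)) next
          gi <- div[ii]
          if (f == "PLB") {
            iso <- .isoCode(isotypeSwitch(rep("IgM", length(ii)),
                                          il4site[ag$pos[gi] + 1L],
                                          cfg$il4Threshold, "PLB"))
            a <- .makeAgents(length(ii), "PLB", pos = ag$pos[gi],
                             receptor = recJ[ii],
                             halfLife = cfg$halfLife$plb, state = "ACTIVE",
                             isotype = iso, uid = uidJ[ii])
          } else if (f == "MEM") {
            a <- .makeAgents(length(ii), "B", pos = ag$pos[gi],
                             receptor = recJ[ii],
                             halfLife = cfg$halfLife$memory, state = "MEMORY",
                             isotype = .isoCode("IgM"), uid = uidJ[ii])
          } else {
            a <- .makeAgents(length(ii), "B", pos = ag$pos[gi],
                             receptor = recJ[ii],
                             halfLife = cfg$halfLife$naive,
                             state = "DUPLICATING",
                             isotype = .isoCode("IgM"), uid = uidJ[ii])
          }
          a$dup <- ag$dup[gi] + 1L
          dl[[length(dl) + 1L]] <- a
        }
      }
      newA <- Reduce(.bindAgents, dl, .emptyAgents())
      keep <- rep(TRUE, .nAgents(ag)); keep[div] <- FALSE
      ag <- .bindAgents(.subsetAgents(ag, keep), newA)
    }
  }

  # duplicating cells at the Hayflick limit terminally differentiate
  bLim <- which(ag$type == .typeCode("B") &
                  ag$state == .stateCode("DUPLICATING") &
                  ag$dup >= cfg$hayflick)
  if (length(bLim)) {
    iso <- vapply(bLim, function(gi)
      .isoCode(isotypeSwitch("IgM", il4site[ag$pos[gi] + 1L],
                             cfg$il4Threshold, "PLB")), 0L)
    ag$type[bLim] <- .typeCode("PLB")
    ag$state[bLim] <- .stateCode("ACTIVE")
    ag$isotype[bLim] <- iso
    ag$halfLife[bLim] <- cfg$halfLife$plb
  }

  # helper/cytotoxic T cells relax back to rest or convert to memory
  tAct <- which(ag$type %in% .typeCode(c("TH1", "TH2", "TC")) &
                  ag$state == .stateCode("ACTIVE"))
  if (length(tAct)) {
    u <- .crnU(st, ag$uid[tAct], 8)
    ag$state[tAct[u < cfg$tCell$pMem]] <- .stateCode("MEMORY")
    rest <- u >= cfg$tCell$pMem & u < cfg$tCell$pMem + cfg$tCell$pRest
    ag$state[tAct[rest]] <- .stateCode("RESTING")
  }

  # presenting APCs eventually return to rest
  apcPres <- which(ag$type %in% .typeCode(c("MONO", "MAC", "DC")) &
                     ag$state %in% .stateCode(c("PRESENTING_II", "PRESENTING_I")))
  if (length(apcPres)) {
    done <- apcPres[.crnU(st, ag$uid[apcPres], 9) < cfg$apcRest]
    ag$state[done] <- .stateCode("RESTING")
    ag$complex[done] <- NA_integer_
  }

  # IL-4 dependent mast-cell growth (suppressible by exposure)
  mast <- which(ag$type == .typeCode("MAST"))
  if (length(mast)) {
    il4 <- il4site[ag$pos[mast] + 1L]
    p <- cfg$mast$pGrow * il4 / (il4 + cfg$mast$k) * st$mult$mastGrowth
    born <- mast[.crnU(st, ag$uid[mast], 10) < p]
    if (length(born)) {
      a <- .makeAgents(length(born), "MAST", pos = ag$pos[born],
                       halfLife = cfg$halfLife$innate,
                       uid = (ag$uid[born] * 4 + 3) %% 9e15)
      ag <- .bindAgents(ag, a)
    }
  }

  # late IgG -> IgA switch of plasma cells
  plbG <- which(ag$type == .typeCode("PLB") & ag$isotype == .isoCode("IgG"))
  if (length(plbG)) {
    sw <- plbG[.crnU(st, ag$uid[plbG], 11) < cfg$pIgA]
    ag$isotype[sw] <- .isoCode("IgA")
  }

  st$agents <- ag
  invisible(st)
}

.phaseSecretion <- function(st) {
  cfg <- st$cfg
  ag <- st$agents
  ns <- nSites(st$lat)
  sec <- ag$comp == .compCode("SECONDARY_ORGAN")
  tab <- cfg$secretion
  for (i in seq_len(nrow(tab))) {
    sel <- sec & ag$type == .typeCode(tab$type[i]) &
      ag$state == .stateCode(tab$state[i])
    if (!any(sel)) next
    add <- tabulate(ag$pos[sel] + 1L, ns) * tab$rate[i] *
      st$mult$cytokine[[tab$species[i]]]
    st$cyt[tab$species[i], ] <- st$cyt[tab$species[i], ] + add
  }
  # plasma cells feed the serum immunoglobulin clonotype pool
  plb <- which(sec & ag$type == .typeCode("PLB"))
  if (length(plb)) {
    key <- paste(ag$receptor[plb], ag$isotype[plb])
    agg <- rowsum(rep(cfg$igRate, length(plb)), key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    para <- vapply(parts, function(x) as.integer(x[1L]), 0L)
    iso <- vapply(parts, function(x) as.integer(x[2L]), 0L)
    .igAdd(st, para, iso, as.numeric(agg))
  }
  invisible(st)
}

.igAdd <- function(st, paratope, isotype, amount) {
  ig <- st$ig
  key <- paste(paratope, isotype)
  have <- paste(ig$paratope, ig$isotype)
  hit <- match(key, have)
  old <- !is.na(hit)
  ig$conc[hit[old]] <- ig$conc[hit[old]] + amount[old]
  if (any(!old)) {
    ig$paratope <- c(ig$paratope, paratope[!old])
    ig$isotype <- c(ig$isotype, isotype[!old])
    ig$conc <- c(ig$conc, amount[!old])
  }
  # clonotype cap: fold the least-abundant clonotypes into the bulk pool
  cap <- st$cfg$clonotypeCap
  if (length(ig$conc) > cap) {
    o <- order(ig$conc, decreasing = TRUE)
    keep <- o[seq_len(cap)]
    lose <- o[-seq_len(cap)]
    for (k in lose) {
      nm <- igIsotypes()[ig$isotype[k]]
      ig$bulk[[nm]] <- ig$bulk[[nm]] + ig$conc[k]
    }
    ig$paratope <- ig$paratope[keep]; ig$isotype <- ig$isotype[keep]
    ig$conc <- ig$conc[keep]
  }
  st$ig <- ig
  invisible(st)
}

.phaseFields <- function(st) {
  cfg <- st$cfg
  st$cyt <- .diffuseMat(st$cyt, cfg$fields$D, st$lat) *
    2^(-1 / cfg$fields$halfLife)
  # antigen units diffuse like agents and decay by binomial thinning,
  # with identity-keyed draws under common random numbers
  for (nm in names(st$antigens)) {
    pos <- st$antigens[[nm]]$pos
    if (!length(pos)) next
    uid <- st$antigens[[nm]]$uid
    pos <- .moveKeyed(st, pos, uid, 15)
    live <- .crnU(st, uid, 16) < 2^(-1 / cfg$antigenHalfLife)
    st$antigens[[nm]]$pos <- pos[live]
    st$antigens[[nm]]$uid <- uid[live]
  }
  dec <- 2^(-1 / cfg$igHalfLife)
  st$ig$conc <- st$ig$conc * dec
  st$ig$bulk <- st$ig$bulk * dec
  invisible(st)
}

# neighbour move with identity-keyed direction draws (falls back to the
# stream-based diffuseAgents without CRN or under hard walls)
.moveKeyed <- function(st, pos, uid, salt) {
  if (is.na(st$seedBase) || st$lat@boundary != "PERIODIC")
    return(diffuseAgents(pos, st$lat))
  if (!length(pos)) return(integer(0))
  dir <- 1L + as.integer(floor(.crnU(st, uid, salt) * 6))
  as.integer(st$lat@nbr[cbind(pos + 1L, dir)])
}

.phaseAgentDiffusion <- function(st) {
  ag <- st$agents
  if (.nAgents(ag)) ag$pos <- .moveKeyed(st, ag$pos, ag$uid, 1)
  st$agents <- ag
  invisible(st)
}

.phaseLifecycle <- function(st) {
  ag <- st$agents
  if (!.nAgents(ag)) return(invisible(st))
  alive <- if (is.na(st$seedBase)) stepLifecycle(ag$halfLife)
           else .crnU(st, ag$uid, 2) < 2^(-1 / ag$halfLife)
  ag <- .subsetAgents(ag, alive)
  ag$age <- ag$age + 1L
  st$agents <- ag
  invisible(st)
}

#' Snapshot the tracked population quantities
#'
#' @param st the state environment.
#' @param antigenIds antigen ids whose specific titres to report.
#' @return Named numeric vector: per-type cell counts, per-species cytokine
#'   totals, and per scheduled antigen the unit count and specific
#'   IgM/IgG/IgA titres.
#' @export
snapshotState <- function(st, antigenIds = names(st$antigens)) {
  ag <- st$agents
  sec <- ag$comp == .compCode("SECONDARY_ORGAN")
  counts <- vapply(cellTypes(), function(tp)
    sum(sec & ag$type == .typeCode(tp)), 0)
  names(counts) <- paste0("n", cellTypes())
  cyt <- rowSums(st$cyt)
  names(cyt) <- cytokineSpecies()
  out <- c(counts, cyt)
  for (aid in antigenIds) {
    adef <- st$antigens[[aid]]
    units <- if (is.null(adef)) 0 else length(adef$pos)
    tit <- c(0, 0, 0)
    if (!is.null(adef))
      tit <- vapply(igIsotypes(), function(i)
        specificTiter(st, adef$epitope, i), 0)
    v <- c(units, tit)
    names(v) <- paste0(aid, c("_units", "_IgM", "_IgG", "_IgA"))
    out <- c(out, v)
  }
  out
}
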