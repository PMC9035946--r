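# Simulation space: 2D hexagonal (odd-r offset, six axial neighbours) or 3D
# cubic (six face neighbours) lattice with periodic or hard-wall boundaries.
# Site indices are 0-based and row-major. The neighbour stencil is precomputed
# once into an (nSites x 6) matrix with NA marking truncated directions under
# hard walls.

#' Discrete simulation lattice
#'
#' @slot geometry \code{"HEX2D"} (L x L, six axial neighbours, odd-r offset
#'   convention) or \code{"CUBIC3D"} (L x L x L, six face neighbours).
#' @slot side integer L.
#' @slot boundary \code{"PERIODIC"} or \code{"HARD_WALL"}.
#' @slot nbr integer matrix (nSites x 6) of 0-based neighbour indices; NA where
#'   a hard wall truncates the stencil.
#' @export
setClass("Lattice",
  representation(geometry = "character", side = "integer",
                 boundary = "character", nbr = "matrix"))

setValidity("Lattice", function(object) {
  msg <- character()
  if (!object@geometry %in% c("HEX2D", "CUBIC3D"))
    msg <- c(msg, "geometry must be HEX2D or CUBIC3D")
  if (!object@boundary %in% c("PERIODIC", "HARD_WALL"))
    msg <- c(msg, "boundary must be PERIODIC or HARD_WALL")
  if (object@side < 2L) msg <- c(msg, "side must be >= 2")
  if (object@geometry == "HEX2D" && object@boundary == "PERIODIC" &&
      object@side %% 2L != 0L)
    msg <- c(msg, "HEX2D with PERIODIC boundaries requires an even side (row-parity consistency of the odd-r stencil)")
  n <- if (object@geometry == "HEX2D") object@side^2 else object@side^3
  if (nrow(object@nbr) != n || ncol(object@nbr) != 6L)
    msg <- c(msg, "nbr must be an (nSites x 6) matrix")
  if (length(msg)) msg else TRUE
})

# odd-r offset stencils: neighbour (dr, dc) pairs by row parity
.hexEven <- cbind(dr = c(-1L, -1L, 0L, 0L, 1L, 1L),
                  dc = c(-1L,  0L, -1L, 1L, -1L, 0L))
.hexOdd  <- cbind(dr = c(-1L, -1L, 0L, 0L, 1L, 1L),
                  dc = c( 0L,  1L, -1L, 1L,  0L, 1L))

.buildNbr <- function(geometry, side, boundary) {
  L <- side
  wrap <- function(i) ((i %% L) + L) %% L
  if (geometry == "HEX2D") {
    n <- L * L
    idx <- 0:(n - 1L)
    r <- idx %/% L; c <- idx %% L
    nbr <- matrix(NA_integer_, n, 6L)
    for (k in 1:6) {
      odd <- r %% 2L == 1L
      dr <- ifelse(odd, .hexOdd[k, 1L], .hexEven[k, 1L])
      dc <- ifelse(odd, .hexOdd[k, 2L], .hexEven[k, 2L])
      rr <- r + dr; cc <- c + dc
      if (boundary == "PERIODIC") {
        nbr[, k] <- wrap(rr) * L + wrap(cc)
      } else {
        ok <- rr >= 0L & rr < L & cc >= 0L & cc < L
        nbr[ok, k] <- rr[ok] * L + cc[ok]
      }
    }
    nbr
  } else {
    n <- L^3
    idx <- 0:(n - 1L)
    z <- idx %/% (L * L); rem <- idx %% (L * L); y <- rem %/% L; x <- rem %% L
    d <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
               c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
    nbr <- matrix(NA_integer_, n, 6L)
    for (k in 1:6) {
      xx <- x + d[k, 1L]; yy <- y + d[k, 2L]; zz <- z + d[k, 3L]
      if (boundary == "PERIODIC") {
        nbr[, k] <- wrap(zz) * L * L + wrap(yy) * L + wrap(xx)
      } else {
        ok <- xx >= 0L & xx < L & yy >= 0L & yy < L & zz >= 0L & zz < L
        nbr[ok, k] <- zz[ok] * L * L + yy[ok] * L + xx[ok]
      }
    }
    nbr
  }
}

#' @param geometry \code{"HEX2D"} or \code{"CUBIC3D"}.
#' @param side lattice side L.
#' @param boundary \code{"PERIODIC"} or \code{"HARD_WALL"}.
#' @rdname Lattice-class
#' @examples
#' lat <- Lattice("HEX2D", side = 8, boundary = "PERIODIC")
#' neighbors(0, lat)
#' @export
Lattice <- function(geometry = c("HEX2D", "CUBIC3D"), side = 16L,
                    boundary = c("PERIODIC", "HARD_WALL")) {
  geometry <- match.arg(geometry); boundary <- match.arg(boundary)
  side <- as.integer(side)
  new("Lattice", geometry = geometry, side = side, boundary = boundary,
      nbr = .buildNbr(geometry, side, boundary))
}

#' Number of sites of a lattice
#' @param lattice a \code{\link{Lattice}}.
#' @export
nSites <- function(lattice) nrow(lattice@nbr)

setMethod("show", "Lattice", function(object) {
  cat(sprintf("Lattice: %s, side %d (%d sites), %s boundaries\n",
              object@geometry, object@side, nSites(object), object@boundary))
})

#' Neighbours of a lattice site
#'
#' Returns the (up to six) adjacent site indices: the six axial neighbours on
#' the hexagonal lattice or the six face-adjacent sites on the cubic lattice.
#' Periodic boundaries wrap; hard walls truncate the stencil.
#'
#' @param site 0-based site index.
#' @param lattice a \code{\link{Lattice}}.
#' @return Integer vector of 0-based neighbour indices (no duplicates, never
#'   containing \code{site} itself for side >= 3).
#' @rdname neighbors
#' @export
setMethod("neighbors", signature(site = "numeric", lattice = "Lattice"),
  function(site, lattice) {
    site <- as.integer(site)
    if (length(site) != 1L || is.na(site) || site < 0L || site >= nSites(lattice))
      stop("site index out of range", call. = FALSE)
    v <- lattice@nbr[site + 1L, ]
    as.integer(v[!is.na(v)])
  })

#' Brownian diffusion of agents on the lattice
#'
#' Moves every agent to a uniformly chosen neighbouring site (all entities
#' share one diffusion coefficient). Under hard walls the draw is made among
#' the existing neighbours only, so there is no sticking bias at the edges.
#'
#' @param pos integer vector of 0-based agent positions (may be empty).
#' @param lattice a \code{\link{Lattice}}.
#' @return Integer vector of updated positions, same length as \code{pos}.
#' @export
diffuseAgents <- function(pos, lattice) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  if (any(pos < 0L) || any(pos >= nSites(lattice)))
    stop("agent position out of range", call. = FALSE)
  nb <- lattice@nbr[pos + 1L, , drop = FALSE]
  if (lattice@boundary == "PERIODIC") {
    j <- sample.int(6L, n, replace = TRUE)
  } else {
    w <- matrix(runif(n * 6L), n, 6L)
    w[is.na(nb)] <- -1
    j <- max.col(w, ties.method = "first")  # uniform among valid directions
  }
  as.integer(nb[cbind(seq_len(n), j)])
}

#' Per-site molecular concentration field
#'
#' One diffusible, decaying species tracked as a non-negative concentration on
#' every lattice site.
#'
#' @slot species character id.
#' @slot conc numeric vector, one non-negative value per site.
#' @slot D diffusion fraction in [0, 1] leaving a site per step.
#' @slot halfLife decay half-life in steps (> 0).
#' @export
setClass("MolecularField",
  representation(species = "character", conc = "numeric",
                 D = "numeric", halfLife = "numeric"))

setValidity("MolecularField", function(object) {
  msg <- character()
  if (any(object@conc < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (object@D < 0 || object@D > 1) msg <- c(msg, "D must be in [0, 1]")
  if (object@halfLife <= 0) msg <- c(msg, "halfLife must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param species character id.
#' @param conc per-site concentrations.
#' @param D diffusion fraction.
#' @param halfLife half-life in steps.
#' @rdname MolecularField-class
#' @export
MolecularField <- function(species, conc, D = 0.3, halfLife = 6) {
  new("MolecularField", species = species, conc = as.numeric(conc),
      D = as.numeric(D), halfLife = as.numeric(halfLife))
}

setMethod("show", "MolecularField", function(object) {
  cat(sprintf("MolecularField '%s': %d sites, total %.4g, D=%.2f, halfLife=%g\n",
              object@species, length(object@conc), sum(object@conc),
              object@D, object@halfLife))
})

# core diffusion kernel on a concentration matrix (rows = species, cols = sites)
.diffuseMat <- function(m, D, lattice) {
  if (D == 0) return(m)
  nb <- lattice@nbr
  if (lattice@boundary == "PERIODIC") {
    out <- m * (1 - D)
    for (k in 1:6) out <- out + (D / 6) * m[, nb[, k] + 1L, drop = FALSE]
    out
  } else {
    k_t <- rowSums(!is.na(nb))          # valid neighbours per source site
    out <- m * (1 - D)
    share <- sweep(m, 2L, D / k_t, "*") # outflow per neighbour, by source
    for (k in 1:6) {
      src <- which(!is.na(nb[, k]))
      dst <- nb[src, k] + 1L
      # accumulate inflow: neighbour relation is symmetric, so iterate sources
      for (i in seq_along(src)) out[, dst[i]] <- out[, dst[i]] + share[, src[i]]
    }
    out
  }
}

#' Diffuse a molecular field for one step
#'
#' Each site keeps a fraction \code{1 - D} of its mass and sends \code{D/k} to
#' each of its \code{k} neighbours. Under periodic boundaries \code{k = 6}
#' everywhere and total mass is conserved exactly; under hard walls the
#' outgoing fraction is split among the existing neighbours only, which also
#' conserves mass.
#'
#' @param field a \code{\link{MolecularField}}.
#' @param lattice the \code{\link{Lattice}} the field lives on.
#' @return The diffused \code{MolecularField}.
#' @export
diffuseField <- function(field, lattice) {
  stopifnot(is(field, "MolecularField"))
  if (field@D < 0 || field@D > 1) stop("D must be in [0, 1]", call. = FALSE)
  if (length(field@conc) != nSites(lattice))
    stop("field length does not match lattice", call. = FALSE)
  m <- .diffuseMat(matrix(field@conc, nrow = 1L), field@D, lattice)
  initialize(field, conc = as.numeric(m))
}

#' Exponential decay of a molecular field
#'
#' Multiplies every site by \code{2^(-1/halfLife)}, so any value halves after
#' exactly \code{halfLife} steps.
#'
#' @param field a \code{\link{MolecularField}}.
#' @return The decayed field.
#' @export
decayField <- function(field) {
  stopifnot(is(field, "MolecularField"))
  if (field@halfLife <= 0) stop("halfLife must be > 0", call. = FALSE)
  initialize(field, conc = field@conc * 2^(-1 / field@halfLife))
}
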