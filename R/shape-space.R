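# Bit-string shape space: receptors, ligands, MHC molecules and peptides are
# unsigned integers interpreted as binary strings of a common global length l.
# Complementarity is measured by the Hamming distance d; differing bits are
# complementary, so affinity increases with d.

.MAX_L <- 30L

#' Affinity parameters for bit-string complementarity matching
#'
#' Bundles the global receptor string length \code{l} with the parameters of
#' the thresholded-exponential binding rule
#' \deqn{p(d) = 0 \;\mathrm{if}\; d < d_{min}; \quad
#'       p(d) = p_{max}\,\alpha^{\,l-d} \;\mathrm{otherwise,}}
#' where \code{d} is the Hamming distance between the two strings. The rule is
#' monotone non-decreasing in the number of complementary (differing) bits and
#' reaches \code{pMax} at perfect complementarity (\code{d = l}).
#'
#' @slot l integer, string length in bits (all strings in one simulation share it).
#' @slot dMin integer, minimum number of complementary bits for any binding.
#' @slot alpha numeric in (0, 1], per-missing-bit penalty.
#' @slot pMax numeric in [0, 1], binding probability at perfect complement.
#' @export
setClass("AffinityParams",
  representation(l = "integer", dMin = "integer", alpha = "numeric", pMax = "numeric"),
  prototype(l = 12L, dMin = 9L, alpha = 0.7, pMax = 1.0)
)

setValidity("AffinityParams", function(object) {
  msg <- character()
  if (length(object@l) != 1L || is.na(object@l) || object@l < 1L || object@l > .MAX_L)
    msg <- c(msg, sprintf("l must be a single integer in [1, %d]", .MAX_L))
  if (length(object@dMin) != 1L || is.na(object@dMin) ||
      object@dMin < 0L || object@dMin > object@l)
    msg <- c(msg, "dMin must satisfy 0 <= dMin <= l")
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be in (0, 1]")
  if (length(object@pMax) != 1L || is.na(object@pMax) ||
      object@pMax < 0 || object@pMax > 1)
    msg <- c(msg, "pMax must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param l integer string length in bits.
#' @param dMin integer binding threshold; default \code{l - 3}.
#' @param alpha per-missing-bit penalty in (0, 1].
#' @param pMax binding probability at perfect complement.
#' @return An \code{AffinityParams} object.
#' @rdname AffinityParams-class
#' @examples
#' ap <- AffinityParams(l = 8, dMin = 5, alpha = 0.5)
#' bindingProbability(0L, 255L, ap)  # perfect complement -> pMax
#' @export
AffinityParams <- function(l = 12L, dMin = as.integer(l) - 3L, alpha = 0.7, pMax = 1.0) {
  new("AffinityParams", l = as.integer(l), dMin = as.integer(dMin),
      alpha = as.numeric(alpha), pMax = as.numeric(pMax))
}

setMethod("show", "AffinityParams", function(object) {
  cat(sprintf("AffinityParams: l=%d bits, dMin=%d, alpha=%.3g, pMax=%.3g\n",
              object@l, object@dMin, object@alpha, object@pMax))
})

.checkBits <- function(x, l, what = "bit string") {
  if (any(is.na(x)) || any(x < 0) || any(x >= 2^l))
    stop(sprintf("invalid %s: values must lie in [0, 2^%d)", what, l), call. = FALSE)
  invisible(TRUE)
}

# vectorized population count for non-negative integers < 2^.MAX_L,
# via a 16-bit lookup table built on first use
.popEnv <- new.env(parent = emptyenv())

.popTable <- function() {
  if (is.null(.popEnv$tbl)) {
    v <- 0:65535
    n <- integer(65536L)
    while (any(v > 0L)) {
      n <- n + (v %% 2L)
      v <- v %/% 2L
    }
    .popEnv$tbl <- n
  }
  .popEnv$tbl
}

.bitCount <- function(x) {
  x <- as.integer(x)
  tbl <- .popTable()
  tbl[x %% 65536L + 1L] + tbl[x %/% 65536L + 1L]
}

#' Hamming distance between two bit strings
#'
#' Counts the bit positions at which \code{a} and \code{b} differ. In the
#' shape-space convention used throughout the package, differing bits are
#' complementary, so larger distances mean stronger receptor-ligand affinity.
#' Vectorized over \code{a} and \code{b} (recycled).
#'
#' @param a,b non-negative integers in \code{[0, 2^l)} encoding bit strings.
#' @param l shared string length in bits.
#' @return Integer vector of distances in \code{[0, l]}.
#' @examples
#' hammingDistance(strtoi("1100", base = 2), strtoi("1010", base = 2), l = 4)  # 2
#' @export
hammingDistance <- function(a, b, l) {
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 1L || l > .MAX_L)
    stop("l must be a single integer in [1, ", .MAX_L, "]", call. = FALSE)
  .checkBits(a, l, "bit string 'a'")
  .checkBits(b, l, "bit string 'b'")
  .bitCount(bitwXor(as.integer(a), as.integer(b)))
}

#' Binding probability from bit-string complementarity
#'
#' Thresholded-exponential map from Hamming distance to the success
#' probability of a specific (receptor-mediated) Bernoulli interaction; see
#' \code{\link{AffinityParams}} for the functional form.
#'
#' @param a,b bit strings (non-negative integers); vectorized with recycling.
#' @param params an \code{\link{AffinityParams}} object carrying \code{l}.
#' @return Numeric vector of probabilities in [0, 1], non-decreasing in the
#'   Hamming distance.
#' @export
bindingProbability <- function(a, b, params) {
  stopifnot(is(params, "AffinityParams"))
  d <- hammingDistance(a, b, params@l)
  ifelse(d < params@dMin, 0, params@pMax * params@alpha^(params@l - d))
}

#' Sample a uniform receptor repertoire
#'
#' Draws \code{n} bit strings uniformly and independently from \code{[0, 2^l)}.
#' The potential repertoire scales as \code{2^l}; sampling is reproducible
#' under a fixed RNG seed.
#'
#' @param n number of strings (>= 0).
#' @param l string length in bits.
#' @param unique draw without replacement (exhaustive-unique mode; requires
#'   \code{n <= 2^l}).
#' @return Integer vector of length \code{n}.
#' @export
sampleRepertoire <- function(n, l, unique = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be >= 0", call. = FALSE)
  l <- as.integer(l)
  if (is.na(l) || l < 1L || l > .MAX_L) stop("invalid l", call. = FALSE)
  if (n == 0L) return(integer(0))
  if (unique && n > 2^l) stop("n exceeds the repertoire size 2^l", call. = FALSE)
  as.integer(sample.int(2^l, n, replace = !unique) - 1L)
}

#' Mutate a receptor by flipping distinct random bits
#'
#' Hypermutation primitive: flips \code{nBits} distinct, uniformly chosen
#' positions of \code{r}, so that the Hamming distance between input and
#' output is exactly \code{nBits}.
#'
#' @param r a bit string (non-negative integer).
#' @param nBits number of positions to flip, in \code{[0, l]}.
#' @param l string length in bits.
#' @return The mutated bit string.
#' @export
mutateReceptor <- function(r, nBits, l) {
  l <- as.integer(l); nBits <- as.integer(nBits)
  if (is.na(nBits) || nBits < 0L || nBits > l)
    stop("nBits must be in [0, l]", call. = FALSE)
  .checkBits(r, l, "receptor")
  if (nBits == 0L) return(as.integer(r))
  pos <- sample.int(l, nBits)
  mask <- sum(bitwShiftL(1L, pos - 1L))
  bitwXor(as.integer(r), as.integer(mask))
}

#' Render a bit string as a 0/1 character string
#' @param x non-negative integer(s).
#' @param l string length in bits.
#' @return Character vector of \code{l}-character 0/1 strings (MSB first).
#' @export
formatBits <- function(x, l) {
  vapply(as.integer(x), function(v)
    paste(rev((v %/% 2^(0:(l - 1))) %% 2), collapse = ""), character(1))
}
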