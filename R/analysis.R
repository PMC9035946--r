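# Trial analytics: population averages, exposure-quartile splits, rank
# exposure-response correlation, and the fold-change effect between paired
# arms, with seeded percentile-bootstrap confidence intervals (2000
# resamples by default).

#' Pointwise population average of a set of time series
#'
#' @param seriesList list of equal-length data.frames as returned by
#'   \code{\link{runSimulation}}.
#' @return List with \code{mean} and \code{sd} data.frames (same shape as
#'   one input series).
#' @export
populationAverage <- function(seriesList) {
  stopifnot(length(seriesList) >= 1L)
  n <- nrow(seriesList[[1L]])
  if (!all(vapply(seriesList, nrow, 0L) == n))
    stop("series must have equal length", call. = FALSE)
  cols <- names(seriesList[[1L]])
  arr <- simplify2array(lapply(seriesList, function(d) as.matrix(d)))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (length(seriesList) > 1L) apply(arr, c(1, 2), sd) else mu * 0
  list(mean = as.data.frame(mu, check.names = FALSE),
       sd = as.data.frame(sdv, check.names = FALSE))
}

#' Split an endpoint table into exposure quartiles
#'
#' Sorts patients by exposure (ascending, ties broken by patient id) and
#' splits them into 4 contiguous groups with sizes as equal as possible,
#' assigning the remainder to the lowest quartiles.
#'
#' @param endpoints data.frame with \code{patient_id} and the split column.
#' @param by name of the exposure column.
#' @return The endpoint table with an added integer \code{quartile} column
#'   (1 = lowest exposure).
#' @export
quartileSplit <- function(endpoints, by = "exposure") {
  n <- nrow(endpoints)
  if (n < 4L) stop("need at least 4 patients for a quartile split", call. = FALSE)
  o <- order(endpoints[[by]], endpoints$patient_id)
  base <- n %/% 4L; rem <- n %% 4L
  sizes <- rep(base, 4L) + as.integer(seq_len(4L) <= rem)
  q <- rep(1:4, times = sizes)
  endpoints$quartile <- NA_integer_
  endpoints$quartile[o] <- q
  endpoints
}

#' Rank correlation between exposure and antibody titre
#'
#' Spearman rank correlation with a seeded percentile-bootstrap confidence
#' interval. With constant titres the correlation is degenerate and reported
#' as 0 with a flag.
#'
#' @param exposures,titers numeric vectors (n >= 3; exposures non-constant).
#' @param conf confidence level.
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return List: \code{rho}, \code{ci} (length 2), \code{degenerate}.
#' @export
exposureResponseCorrelation <- function(exposures, titers, conf = 0.95,
                                        nBoot = 2000L, seed = 1L) {
  n <- length(exposures)
  if (n < 3L || length(titers) != n)
    stop("need n >= 3 paired observations", call. = FALSE)
  if (sd(exposures) == 0) stop("exposures are constant", call. = FALSE)
  if (sd(titers) == 0)
    return(list(rho = 0, ci = c(0, 0), degenerate = TRUE))
  rho <- cor(exposures, titers, method = "spearman")
  set.seed(seed)
  bs <- replicate(nBoot, {
    i <- sample.int(n, n, replace = TRUE)
    if (sd(titers[i]) == 0 || sd(exposures[i]) == 0) NA_real_
    else cor(exposures[i], titers[i], method = "spearman")
  })
  a <- (1 - conf) / 2
  list(rho = rho,
       ci = unname(quantile(bs, c(a, 1 - a), na.rm = TRUE)),
       degenerate = FALSE)
}

#' Fold-change effect between a reference and a doubled-exposure arm
#'
#' Percent difference of the higher-exposure arm's mean endpoint relative to
#' the reference arm: \code{100 * (mean(x2) - mean(ref)) / mean(ref)}, with a
#' seeded percentile-bootstrap confidence interval.
#'
#' @param endpointsRef,endpoints2x numeric endpoint vectors (non-empty).
#' @param conf confidence level.
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return List: \code{effect} (percent), \code{ci} (length 2).
#' @export
foldChangeEffect <- function(endpointsRef, endpoints2x, conf = 0.95,
                             nBoot = 2000L, seed = 1L) {
  if (!length(endpointsRef) || !length(endpoints2x))
    stop("endpoint sets must be non-empty", call. = FALSE)
  mRef <- mean(endpointsRef)
  if (mRef == 0) stop("undefined effect: reference mean is 0", call. = FALSE)
  eff <- 100 * (mean(endpoints2x) - mRef) / mRef
  set.seed(seed)
  bs <- replicate(nBoot, {
    r <- mean(sample(endpointsRef, replace = TRUE))
    x <- mean(sample(endpoints2x, replace = TRUE))
    if (r == 0) NA_real_ else 100 * (x - r) / r
  })
  a <- (1 - conf) / 2
  list(effect = eff,
       ci = unname(quantile(bs, c(a, 1 - a), na.rm = TRUE)))
}
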