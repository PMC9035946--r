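#' @import methods
#' @importFrom stats runif rnorm rbinom setNames quantile cor sd
#' @importFrom utils head tail
NULL

#' @rdname neighbors
#' @export
setGeneric("neighbors", function(site, lattice) standardGeneric("neighbors"))

#' @rdname serumConcentration
#' @export
setGeneric("serumConcentration", function(profile, t) standardGeneric("serumConcentration"))

#' @rdname validatePatient
#' @export
setGeneric("validatePatient", function(patient, spec) standardGeneric("validatePatient"))
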