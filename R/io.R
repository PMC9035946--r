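# Delimited outputs and run manifests. Floats are written at 17 significant
# digits so that re-runs can be compared byte for byte.

.fmt17 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else x
}

#' Write a time-series table in long format
#'
#' Columns: \code{step}, \code{day}, \code{quantity}, \code{value},
#' \code{patient_id}; floats at 17 significant digits.
#'
#' @param series a wide series from \code{\link{runSimulation}}, or a list of
#'   them (one per patient).
#' @param path output CSV path.
#' @export
writeTimeseriesCsv <- function(series, path) {
  if (is.data.frame(series)) series <- list(series)
  rows <- lapply(seq_along(series), function(i) {
    d <- series[[i]]
    qcols <- setdiff(names(d), c("step", "day"))
    data.frame(step = rep(d$step, length(qcols)),
               day = rep(d$day, length(qcols)),
               quantity = rep(qcols, each = nrow(d)),
               value = unlist(d[qcols], use.names = FALSE),
               patient_id = i)
  })
  long <- do.call(rbind, rows)
  long$value <- sprintf("%.17g", long$value)
  long$day <- sprintf("%.17g", long$day)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an endpoint table
#' @param endpoints endpoint data.frame from a \code{\link{TrialResult}}.
#' @param path output CSV path.
#' @export
writeEndpointsCsv <- function(endpoints, path) {
  out <- endpoints
  for (nm in names(out)) if (is.double(out[[nm]]))
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#' @param manifest named list (seeds, config hash, version, ...).
#' @param path output JSON path.
#' @export
writeManifestJson <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Hash a configuration list
#'
#' Deterministic content hash of the serialized configuration, for manifests.
#' @param cfg a configuration list.
#' @export
configHash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 17,
                                              list.len = 1e4)),
             collapse = "\n")
  # FNV-1a over the serialized text, hex encoded
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
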