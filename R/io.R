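#' Text I/O: FID files, priors, fit reports
#'
#' Plain-text interchange formats: a two-column real/imaginary FID file
#' with a small header (the jMRUI-style ASCII convention), a TSV format
#' for peak priors, and JSON-lines fit reports.
#'
#' @name text_io
NULL

#' Write / read an FID as two-column ASCII text
#'
#' Header lines carry the sampling interval (ms), transmitter frequency
#' (Hz) and reference shift; the body is one `real imaginary` pair per
#' point.
#'
#' @param fid An [fid_signal()].
#' @param path File path.
#' @return `write_fid_text`: `path` invisibly; `read_fid_text`: an
#'   [fid_signal()].
#' @export
write_fid_text <- function(fid, path) {
  stopifnot(inherits(fid, "fid_signal"))
  acq <- fid$acq
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("mrsimm FID text v1",
               sprintf("SamplingInterval: %.17g", acq$dwell_time * 1e3),
               sprintf("TransmitterFrequency: %.17g", acq$transmitter_frequency * 1e6),
               sprintf("ReferencePPM: %.17g", acq$reference_ppm),
               sprintf("PointsNumber: %d", acq$n_points),
               "Signal (real imaginary):"), con)
  writeLines(sprintf("%.17g %.17g", Re(fid$samples), Im(fid$samples)), con)
  invisible(path)
}

#' @rdname write_fid_text
#' @export
read_fid_text <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)[1]
    as.numeric(sub(paste0(key, ":\\s*"), "", ln))
  }
  dwell <- grab("SamplingInterval") * 1e-3
  tf <- grab("TransmitterFrequency") * 1e-6
  ref <- grab("ReferencePPM")
  n <- as.integer(grab("PointsNumber"))
  start <- grep("^Signal", lines)[1] + 1
  body <- lines[start:(start + n - 1)]
  parts <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                  ncol = 2, byrow = TRUE)
  acq <- acq_params(dwell_time = dwell, n_points = n,
                    transmitter_frequency = tf, reference_ppm = ref)
  fid_signal(complex(real = parts[, 1], imaginary = parts[, 2]), acq)
}

#' Write / read peak priors as TSV
#'
#' @param priors A [peak_priors()] table.
#' @param path File path.
#' @return `write_priors_tsv`: `path` invisibly; `read_priors_tsv`: a
#'   `peak_priors` table.
#' @export
write_priors_tsv <- function(priors, path) {
  utils::write.table(priors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_priors_tsv
#' @export
read_priors_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("peak_priors", "data.frame")
  d
}

#' Write a fit report as JSON lines
#'
#' One JSON object per component with amplitude, CRLB and line parameters;
#' works for both `amares_fit` and `lc_fit_result` objects.
#'
#' @param fit An `amares_fit` or `lc_fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rows <- if (inherits(fit, "amares_fit")) {
    lapply(seq_len(nrow(fit$components)), function(j)
      as.list(fit$components[j, c("name", "center_ppm", "fwhm_hz",
                                  "amplitude", "phase_deg", "crlb_amp_pct")]))
  } else if (inherits(fit, "lc_fit_result")) {
    lapply(names(fit$amplitudes), function(nm)
      list(name = nm, amplitude = unname(fit$amplitudes[nm]),
           crlb_percent = unname(fit$crlb_percent[nm])))
  } else stop("unsupported fit object")
  con <- file(path, "w")
  on.exit(close(con))
  for (r in rows)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}
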