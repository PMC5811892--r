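#' Macromolecule component tables and MM models
#'
#' An MM model is a named collection of basis FIDs representing the
#' macromolecule background in one of seven variants:
#'
#' * `full_MM` — one component, the full (averaged, residual-cleaned)
#'   metabolite-nulled spectrum;
#' * `ind_MM_AM` / `ind_MM_HL` — nine individual components from the
#'   AMARES-style or HLSVD-style parameterization;
#' * `grp_MM_AM` / `grp_MM_HL` — the nine components merged into four
#'   fixed groups (MM1-MM4, MM5-MM6, MM7-MM8, MM9);
#' * `con_MM_AM` / `con_MM_HL` — the nine individual components plus soft
#'   concentration-ratio priors MM(XX)/MM1.
#'
#' @name mm_model
NULL

mm_variants <- c("full_MM", "ind_MM_HL", "ind_MM_AM", "grp_MM_HL",
                 "grp_MM_AM", "con_MM_HL", "con_MM_AM")

#' Construct an MM model
#'
#' @param variant One of `full_MM`, `ind_MM_HL`, `ind_MM_AM`, `grp_MM_HL`,
#'   `grp_MM_AM`, `con_MM_HL`, `con_MM_AM`.
#' @param fids Named list of complex basis FIDs (all on the same grid).
#' @param acq An [acq_params()] object.
#' @param components Optional data frame of per-component parameters
#'   (`name`, `center_ppm`, `fwhm_hz`, `amplitude`, `phase_deg`,
#'   `lineshape`); present for parameterized variants.
#' @param ratio_priors Optional data frame of soft ratio priors (see
#'   [derive_ratio_priors()]); required for `con_*` variants, forbidden
#'   otherwise.
#' @param provenance Free-text origin label (e.g. `"AMARES"`, `"HLSVD"`,
#'   `"measured-analog"`).
#' @return An object of class `mm_model`.
#' @export
mm_model <- function(variant, fids, acq, components = NULL,
                     ratio_priors = NULL, provenance = variant) {
  variant <- match.arg(variant, mm_variants)
  stopifnot(inherits(acq, "acq_params"), is.list(fids), length(fids) >= 1)
  if (is.null(names(fids)) || anyDuplicated(names(fids)))
    stop("MM component FIDs must have unique names")
  n_expected <- switch(substr(variant, 1, 3),
                       ful = 1L, ind = 9L, con = 9L, grp = 4L)
  if (length(fids) != n_expected)
    stop(variant, " requires exactly ", n_expected, " components, got ",
         length(fids))
  if (startsWith(variant, "con")) {
    if (is.null(ratio_priors)) stop("con_* variants require ratio_priors")
  } else if (!is.null(ratio_priors)) {
    stop("ratio priors are only carried by con_* variants")
  }
  for (f in fids)
    if (length(f) != acq$n_points) stop("component FID length != acq$n_points")
  structure(list(variant = variant, fids = lapply(fids, as.complex),
                 acq = acq, components = components,
                 ratio_priors = ratio_priors, provenance = provenance),
            class = "mm_model")
}

#' @export
print.mm_model <- function(x, ...) {
  cat(sprintf("<mm_model> %s (%s): %s\n", x$variant, x$provenance,
              paste(names(x$fids), collapse = ", ")))
  if (!is.null(x$ratio_priors))
    cat(sprintf("  %d ratio priors vs %s\n", nrow(x$ratio_priors),
                attr(x$ratio_priors, "denominator") %||% "MM1"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The nine macromolecule peak positions (ppm)
#'
#' Chemical shifts of the nine parameterized MM peaks MM1-MM9. The tenth MM
#' resonance near 4.3 ppm is deliberately absent: it sits too close to the
#' water peak to be parameterized.
#' @return Named numeric vector of length 9.
#' @export
mm_peak_positions <- function() {
  c(MM1 = 0.90, MM2 = 1.21, MM3 = 1.43, MM4 = 1.67, MM5 = 2.04,
    MM6 = 2.26, MM7 = 2.99, MM8 = 3.21, MM9 = 3.77)
}

#' Ground-truth MM component table for synthetic spectra
#'
#' Gaussian components at the nine standard MM positions. Positions are the
#' literature values; amplitudes and widths are fixture choices (amplitudes
#' follow the visual prominence order MM1 >= MM9 >= MM5 > others, widths
#' 0.04-0.12 ppm) because true in vivo amplitude ratios are not available.
#'
#' @param acq An [acq_params()] object (converts widths from ppm to Hz).
#' @return Data frame with columns `name`, `center_ppm`, `fwhm_hz`,
#'   `amplitude`, `phase_deg`, `lineshape`.
#' @export
default_mm_truth <- function(acq = acq_nulled_7t()) {
  pos <- mm_peak_positions()
  fwhm_ppm <- c(0.045, 0.075, 0.085, 0.120, 0.075, 0.100, 0.060, 0.070, 0.100)
  amp <- c(1.00, 0.45, 0.40, 0.30, 0.70, 0.50, 0.45, 0.40, 0.75)
  data.frame(name = names(pos), center_ppm = unname(pos),
             fwhm_hz = fwhm_ppm * acq$transmitter_frequency,
             amplitude = amp, phase_deg = 0,
             lineshape = "gaussian", stringsAsFactors = FALSE)
}

# Synthesize one damped sinusoid on the acquisition grid.
# Gaussian decay exp(-beta t^2), beta = (pi*FWHM)^2 / (4 ln 2);
# Lorentzian decay exp(-pi*FWHM*t). Phase in degrees, center in ppm.
component_fid_values <- function(center_ppm, fwhm_hz, amplitude, phase_deg,
                                 lineshape, acq) {
  t <- acq_time_axis(acq)
  f <- ppm_to_hz(center_ppm, acq)
  decay <- if (identical(lineshape, "lorentzian")) {
    exp(-pi * fwhm_hz * t)
  } else {
    beta <- (pi * fwhm_hz)^2 / (4 * log(2))
    exp(-beta * t^2)
  }
  amplitude * exp(1i * phase_deg * pi / 180) * exp(2i * pi * f * t) * decay
}

# FIDs for every row of a component table, as a named list.
component_fid_list <- function(components, acq) {
  out <- lapply(seq_len(nrow(components)), function(j) {
    with(components[j, ], component_fid_values(center_ppm, fwhm_hz, amplitude,
                                               phase_deg, lineshape, acq))
  })
  names(out) <- components$name
  out
}

#' Build an individual-component MM model from a parameter table
#'
#' @param components Component table as in [default_mm_truth()].
#' @param acq An [acq_params()] object.
#' @param provenance Origin label, `"AMARES"` or `"HLSVD"`.
#' @return An `mm_model` of variant `ind_MM_AM` or `ind_MM_HL`.
#' @export
mm_model_from_components <- function(components, acq,
                                     provenance = c("AMARES", "HLSVD")) {
  provenance <- match.arg(provenance)
  stopifnot(nrow(components) >= 1)
  variant <- if (provenance == "AMARES") "ind_MM_AM" else "ind_MM_HL"
  mm_model(variant, component_fid_list(components, acq), acq,
           components = components, provenance = provenance)
}

#' Attach soft ratio priors, turning an ind_* model into a con_* model
#'
#' @param model An `mm_model` of variant `ind_MM_AM` or `ind_MM_HL`.
#' @param ratio_priors Data frame from [derive_ratio_priors()].
#' @return The corresponding `con_MM_AM` / `con_MM_HL` model.
#' @export
mm_model_with_priors <- function(model, ratio_priors) {
  stopifnot(inherits(model, "mm_model"))
  if (!startsWith(model$variant, "ind"))
    stop("ratio priors can only be attached to an ind_* model")
  variant <- sub("^ind", "con", model$variant)
  mm_model(variant, model$fids, model$acq, components = model$components,
           ratio_priors = ratio_priors, provenance = model$provenance)
}

#' Build the single-component full_MM model from nulled FIDs
#'
#' Averages residual-cleaned metabolite-nulled FIDs into one basis
#' component, the conventional "measured MM spectrum" model. With synthetic
#' inputs the provenance is labeled `"measured-analog"`.
#'
#' @param nulled_fids List of [fid_signal()] objects (residuals removed).
#' @param name Component name, default `"MM_full"`.
#' @return An `mm_model` of variant `full_MM`.
#' @export
full_mm_model <- function(nulled_fids, name = "MM_full") {
  stopifnot(length(nulled_fids) >= 1)
  acq <- nulled_fids[[1]]$acq
  mat <- sapply(nulled_fids, function(f) {
    stopifnot(inherits(f, "fid_signal"), f$acq$n_points == acq$n_points)
    f$samples
  })
  avg <- if (is.matrix(mat)) rowMeans(mat) else mat
  fids <- stats::setNames(list(avg), name)
  mm_model("full_MM", fids, acq, provenance = "measured-analog")
}
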