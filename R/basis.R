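#' Basis sets: metabolites + macromolecule model (+ lipids)
#'
#' A basis set is a named collection of FIDs sharing one acquisition grid:
#' 17 simulated metabolite signals, the components of one MM model variant,
#' and optionally broad lipid components. Soft concentration-ratio priors
#' travel with the basis when the MM model carries them.
#'
#' @name basis_set
NULL

#' Construct a basis set
#'
#' @param entries Named list of complex FIDs on the grid of `acq`.
#' @param acq An [acq_params()] object.
#' @param meta List of provenance metadata (`mm_variant`, `n_truncate`, ...).
#' @param ratio_priors Optional ratio-prior data frame.
#' @param lipid_names Character vector naming the entries that are lipid
#'   components (they get wider frequency-shift freedom in the LC fit).
#' @param metabolite_names Names of the metabolite entries.
#' @param mm_names Names of the MM entries.
#' @return An object of class `basis_set`.
#' @export
basis_set <- function(entries, acq, meta = list(), ratio_priors = NULL,
                      lipid_names = character(0),
                      metabolite_names = character(0),
                      mm_names = character(0)) {
  stopifnot(inherits(acq, "acq_params"), is.list(entries), length(entries) >= 1)
  if (is.null(names(entries)) || anyDuplicated(names(entries)))
    stop("basis entries must have unique names")
  for (e in entries)
    if (length(e) != acq$n_points) stop("basis entry length != acq$n_points")
  structure(list(entries = lapply(entries, as.complex), acq = acq,
                 meta = meta, ratio_priors = ratio_priors,
                 lipid_names = lipid_names,
                 metabolite_names = metabolite_names,
                 mm_names = mm_names),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %d entries (%d metabolites, %d MM, %d lipids), %s\n",
              length(x$entries), length(x$metabolite_names),
              length(x$mm_names), length(x$lipid_names),
              x$meta$mm_variant %||% "no MM variant"))
  invisible(x)
}

#' Assemble a complete basis set from metabolites and an MM model
#'
#' Simulates all metabolite line groups (dropping the first `n_truncate`
#' oversampled points, i.e. the acquisition delay) and attaches the MM
#' model components; ratio priors carried by a `con_*` model travel with
#' the basis. Deterministic: the same configuration always produces the
#' same basis.
#'
#' @param metabolite_groups Named list of [line_group()]s
#'   (default: the 17 standard groups of [metabolite_line_groups()]).
#' @param mm_model An `mm_model`.
#' @param acq An [acq_params()] object.
#' @param with_lipids Append the default lipid components
#'   (see [add_simulated_lipids()]).
#' @param n_truncate Oversampled points dropped from the metabolite FIDs.
#' @return A `basis_set`.
#' @export
build_basis <- function(metabolite_groups = metabolite_line_groups(),
                        mm_model, acq = mm_model$acq, with_lipids = FALSE,
                        n_truncate = 39) {
  stopifnot(inherits(mm_model, "mm_model"))
  if (acq$n_points != mm_model$acq$n_points ||
      acq$dwell_time != mm_model$acq$dwell_time)
    stop("mm_model components are not on the basis acquisition grid")
  met <- lapply(metabolite_groups, function(g)
    simulate_metabolite_fid(g, acq, n_truncate = n_truncate)$samples)
  names(met) <- vapply(metabolite_groups, `[[`, "", "metabolite_name")
  entries <- c(met, mm_model$fids)
  if (anyDuplicated(names(entries)))
    stop("duplicate basis entry names: ",
         paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "))
  b <- basis_set(entries, acq,
                 meta = list(mm_variant = mm_model$variant,
                             mm_provenance = mm_model$provenance,
                             n_truncate = n_truncate),
                 ratio_priors = mm_model$ratio_priors,
                 metabolite_names = names(met),
                 mm_names = names(mm_model$fids))
  if (with_lipids) b <- add_simulated_lipids(b)
  b
}

#' Merge the nine MM components into the four standard groups
#'
#' Groups are MM1-MM4 (0.9-1.6 ppm), MM5-MM6, MM7-MM8, and MM9 (a
#' singleton), formed by complex summation of the member FIDs with their
#' relative amplitudes and phases frozen at the parameterization values.
#'
#' @param model An `mm_model` with exactly the nine components MM1..MM9.
#' @return An `mm_model` of variant `grp_MM_AM` / `grp_MM_HL`.
#' @export
group_mm_components <- function(model) {
  stopifnot(inherits(model, "mm_model"))
  groups <- list(MM1_4 = paste0("MM", 1:4), MM5_6 = paste0("MM", 5:6),
                 MM7_8 = paste0("MM", 7:8), MM9 = "MM9")
  missing <- setdiff(unlist(groups), names(model$fids))
  if (length(missing))
    stop("missing MM component(s): ", paste(missing, collapse = ", "))
  fids <- lapply(groups, function(members)
    Reduce(`+`, model$fids[members]))
  variant <- if (model$provenance == "HLSVD") "grp_MM_HL" else "grp_MM_AM"
  mm_model(variant, fids, model$acq, components = model$components,
           provenance = model$provenance)
}

#' Derive soft concentration-ratio priors from nulled spectra
#'
#' Quantifies every MM peak in each metabolite-nulled spectrum with the
#' nine-Gaussian prior-knowledge fit, then for each peak other than MM1
#' (the denominator: easy to quantify, free of metabolite overlap) forms
#' the ratio amplitude(MMx)/amplitude(MM1). The prior expectation is the
#' mean ratio across spectra and the prior SD the sample SD, floored at
#' `sd_floor` times the mean so noiseless inputs cannot produce degenerate
#' hard constraints.
#'
#' @param nulled_fids List of >= 2 residual-cleaned [fid_signal()]s.
#' @param priors Peak priors for the fit ([default_mm_priors()]).
#' @param sd_floor SD floor as a fraction of the mean ratio (default 0.1).
#' @param ... Passed to [amares_fit()].
#' @return Data frame of class `ratio_priors` with columns `numerator`
#'   (component name), `expected_ratio`, `sd`; attribute `denominator`
#'   = `"MM1"`.
#' @export
derive_ratio_priors <- function(nulled_fids, priors = default_mm_priors(),
                                sd_floor = 0.1, ...) {
  stopifnot(length(nulled_fids) >= 2)
  ratios <- NULL
  for (i in seq_along(nulled_fids)) {
    fit <- amares_fit(nulled_fids[[i]], priors, ...)
    comp <- fit$components[order(fit$components$center_ppm), ]
    comp$name <- paste0("MM", seq_len(nrow(comp)))
    a1 <- comp$amplitude[comp$name == "MM1"]
    if (length(a1) == 0 || a1 <= 0) {
      warning("MM1 amplitude <= 0 in spectrum ", i, "; excluded")
      next
    }
    r <- comp$amplitude[comp$name != "MM1"] / a1
    names(r) <- comp$name[comp$name != "MM1"]
    ratios <- rbind(ratios, r)
  }
  if (is.null(ratios) || nrow(ratios) < 1)
    stop("no usable spectra for ratio priors")
  m <- colMeans(ratios)
  s <- if (nrow(ratios) > 1) apply(ratios, 2, stats::sd) else rep(0, length(m))
  s <- pmax(s, sd_floor * m)
  out <- data.frame(numerator = names(m), expected_ratio = unname(m),
                    sd = unname(s), stringsAsFactors = FALSE)
  attr(out, "denominator") <- "MM1"
  class(out) <- c("ratio_priors", "data.frame")
  out
}

#' Append simulated lipid components to a basis set
#'
#' Adds broad Lorentzian lipid components (defaults: 0.9 and 1.3 ppm, FWHM
#' 0.15 ppm) to improve the handling of extracerebral lipid signal in the
#' 1.2-1.4 ppm region. Lipid entries are flagged shift-mobile: the LC fit
#' allows them a larger frequency shift (+/- 0.05 ppm) than metabolites.
#'
#' @param basis A `basis_set`.
#' @param lipid_spec Data frame with columns `name`, `center_ppm`,
#'   `fwhm_ppm`.
#' @return The extended `basis_set`.
#' @export
add_simulated_lipids <- function(basis,
                                 lipid_spec = data.frame(
                                   name = c("Lip09", "Lip13"),
                                   center_ppm = c(0.9, 1.3),
                                   fwhm_ppm = c(0.15, 0.15))) {
  stopifnot(inherits(basis, "basis_set"))
  clash <- intersect(lipid_spec$name, names(basis$entries))
  if (length(clash)) stop("lipid name collision: ", paste(clash, collapse = ", "))
  acq <- basis$acq
  lip <- lapply(seq_len(nrow(lipid_spec)), function(j)
    component_fid_values(lipid_spec$center_ppm[j],
                         lipid_spec$fwhm_ppm[j] * acq$transmitter_frequency,
                         1, 0, "lorentzian", acq))
  names(lip) <- lipid_spec$name
  basis_set(c(basis$entries, lip), acq, meta = basis$meta,
            ratio_priors = basis$ratio_priors,
            lipid_names = c(basis$lipid_names, lipid_spec$name),
            metabolite_names = basis$metabolite_names,
            mm_names = basis$mm_names)
}

#' Write / read a basis set as plain text
#'
#' A simple documented text format modeled on linear-combination basis
#' conventions: a header with the acquisition grid and provenance, one
#' `RATIO` record per soft ratio prior, then per entry a `ENTRY <name>
#' <role>` line followed by `n_points` rows of real and imaginary parts.
#' Round-trips exactly at full double precision.
#'
#' @param basis A `basis_set`.
#' @param path File path.
#' @return `write_basis`: `path`, invisibly. `read_basis`: a `basis_set`.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "basis_set"))
  con <- file(path, "w")
  on.exit(close(con))
  acq <- basis$acq
  writeLines(c(
    "# mrsimm basis set v1",
    sprintf("DWELL %.17g", acq$dwell_time),
    sprintf("TRANSMITTER_MHZ %.17g", acq$transmitter_frequency),
    sprintf("REFERENCE_PPM %.17g", acq$reference_ppm),
    sprintf("N_POINTS %d", acq$n_points),
    sprintf("MM_VARIANT %s", basis$meta$mm_variant %||% "none"),
    sprintf("N_TRUNCATE %d", basis$meta$n_truncate %||% 0L)), con)
  if (!is.null(basis$ratio_priors)) {
    for (i in seq_len(nrow(basis$ratio_priors)))
      writeLines(sprintf("RATIO %s MM1 %.17g %.17g",
                         basis$ratio_priors$numerator[i],
                         basis$ratio_priors$expected_ratio[i],
                         basis$ratio_priors$sd[i]), con)
  }
  for (nm in names(basis$entries)) {
    role <- if (nm %in% basis$mm_names) "mm"
            else if (nm %in% basis$lipid_names) "lipid" else "metabolite"
    writeLines(sprintf("ENTRY %s %s", nm, role), con)
    v <- basis$entries[[nm]]
    writeLines(sprintf("%.17g %.17g", Re(v), Im(v)), con)
  }
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1]
    if (is.na(ln)) stop("missing header field: ", key)
    strsplit(ln, " ", fixed = TRUE)[[1]][-1]
  }
  acq <- acq_params(dwell_time = as.numeric(kv("DWELL")[1]),
                    n_points = as.integer(kv("N_POINTS")[1]),
                    transmitter_frequency = as.numeric(kv("TRANSMITTER_MHZ")[1]),
                    reference_ppm = as.numeric(kv("REFERENCE_PPM")[1]))
  variant <- kv("MM_VARIANT")[1]
  n_trunc <- as.integer(kv("N_TRUNCATE")[1])
  rp_lines <- lines[startsWith(lines, "RATIO ")]
  ratio_priors <- NULL
  if (length(rp_lines)) {
    parts <- do.call(rbind, strsplit(rp_lines, " ", fixed = TRUE))
    ratio_priors <- data.frame(numerator = parts[, 2],
                               expected_ratio = as.numeric(parts[, 4]),
                               sd = as.numeric(parts[, 5]),
                               stringsAsFactors = FALSE)
    attr(ratio_priors, "denominator") <- "MM1"
    class(ratio_priors) <- c("ratio_priors", "data.frame")
  }
  ent_idx <- which(startsWith(lines, "ENTRY "))
  entries <- list(); roles <- character(0)
  for (i in ent_idx) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    block <- lines[(i + 1):(i + acq$n_points)]
    parts <- matrix(as.numeric(unlist(strsplit(block, " ", fixed = TRUE))),
                    ncol = 2, byrow = TRUE)
    entries[[hdr[2]]] <- complex(real = parts[, 1], imaginary = parts[, 2])
    roles[hdr[2]] <- hdr[3]
  }
  basis_set(entries, acq,
            meta = list(mm_variant = if (variant == "none") NULL else variant,
                        n_truncate = n_trunc),
            ratio_priors = ratio_priors,
            lipid_names = names(roles)[roles == "lipid"],
            metabolite_names = names(roles)[roles == "metabolite"],
            mm_names = names(roles)[roles == "mm"])
}
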