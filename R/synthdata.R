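#' Synthetic-data generators
#'
#' Everything the rest of the toolkit consumes can be generated here:
#' simulated metabolite basis FIDs, synthetic metabolite-nulled MM spectra,
#' and full 2D FID-MRSI phantoms with per-voxel ground truth. All
#' generators are pure functions of their parameters and seed.
#'
#' @name synthdata
NULL

# Run code with a private RNG stream; restores the caller's .Random.seed.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

complex_noise <- function(n, sd) {
  complex(real = stats::rnorm(n, sd = sd), imaginary = stats::rnorm(n, sd = sd))
}

#' Weak-coupling line group describing one metabolite
#'
#' A metabolite is modeled as a list of resonance lines (chemical shift +
#' relative amplitude per proton group) sharing a common effective T2*.
#' This is a weak-coupling description: at an acquisition delay of 1.3 ms
#' J-evolution is negligible, so density-matrix simulation is not needed.
#'
#' @param metabolite_name Label.
#' @param shifts_ppm Chemical shifts of the lines (ppm).
#' @param rel_amps Relative amplitudes (>= 0, sum > 0).
#' @param t2_star Effective T2* in seconds (Lorentzian decay).
#' @return An object of class `line_group`.
#' @export
line_group <- function(metabolite_name, shifts_ppm, rel_amps, t2_star = 0.08) {
  stopifnot(length(shifts_ppm) == length(rel_amps), length(shifts_ppm) >= 1,
            all(rel_amps >= 0), sum(rel_amps) > 0, t2_star > 0)
  structure(list(metabolite_name = metabolite_name,
                 lines = data.frame(shift_ppm = shifts_ppm, rel_amp = rel_amps),
                 t2_star = t2_star),
            class = "line_group")
}

#' The 17 standard metabolite line groups
#'
#' Line lists for the 17 simulated metabolite signals of the standard 7T
#' basis: glucose, aspartate, the two cholines (GPC, PCh), the two
#' creatines (Cr, PCr), GABA, glutamate, glutamine, glutathione, glycine,
#' lactate, myo-inositol, NAA, NAAG, scyllo-inositol and taurine. Shifts
#' are standard literature values restricted to the 0.2-4.2 ppm analysis
#' window; relative amplitudes reflect proton counts of the main groups.
#'
#' @param t2_star Common effective T2* in seconds.
#' @return Named list of 17 [line_group()] objects.
#' @export
metabolite_line_groups <- function(t2_star = 0.08) {
  lg <- function(name, s, a) line_group(name, s, a, t2_star)
  list(
    Glc  = lg("Glc",  c(3.23, 3.40, 3.47, 3.53, 3.71, 3.84), c(1, 2, 2, 2, 2, 1)),
    Asp  = lg("Asp",  c(2.66, 2.80, 3.89), c(1, 1, 1)),
    GPC  = lg("GPC",  c(3.212, 3.66, 3.90), c(9, 2, 2)),
    PCh  = lg("PCh",  c(3.208, 3.58, 4.16), c(9, 2, 2)),
    Cr   = lg("Cr",   c(3.027, 3.913), c(3, 2)),
    PCr  = lg("PCr",  c(3.029, 3.930), c(3, 2)),
    GABA = lg("GABA", c(1.89, 2.28, 3.01), c(2, 2, 2)),
    Glu  = lg("Glu",  c(2.04, 2.12, 2.35, 3.75), c(1, 1, 2, 1)),
    Gln  = lg("Gln",  c(2.13, 2.45, 3.76), c(2, 2, 1)),
    GSH  = lg("GSH",  c(2.15, 2.55, 2.95, 3.77), c(2, 2, 2, 1)),
    Gly  = lg("Gly",  3.55, 2),
    Lac  = lg("Lac",  c(1.31, 4.10), c(3, 1)),
    Ins  = lg("Ins",  c(3.27, 3.52, 3.61, 4.05), c(1, 2, 2, 1)),
    NAA  = lg("NAA",  c(2.008, 2.49, 2.67), c(3, 1, 1)),
    NAAG = lg("NAAG", c(2.042, 2.52, 3.76), c(3, 1, 1)),
    sIns = lg("sIns", 3.34, 6),
    Tau  = lg("Tau",  c(3.25, 3.42), c(2, 2))
  )
}

#' Simulate a metabolite basis FID (hard-pulse FID acquisition)
#'
#' Simulates `sum_l a_l * exp(2i*pi*f_l*t) * exp(-t/T2*)` on an internally
#' oversampled grid (`oversample` times the acquisition bandwidth), drops
#' the first `n_truncate` internal points to emulate the acquisition delay
#' (at the default 5x oversampling of a 6,000 Hz acquisition, 39 points =
#' 1.3 ms = TE*), and evaluates the remaining analytic signal exactly on
#' the acquisition grid. Deterministic.
#'
#' @param group A [line_group()].
#' @param acq An [acq_params()] object.
#' @param n_truncate Internal points to drop (default 39).
#' @param oversample Internal bandwidth multiplier (default 5).
#' @return An [fid_signal()].
#' @export
simulate_metabolite_fid <- function(group, acq, n_truncate = 39, oversample = 5) {
  stopifnot(inherits(group, "line_group"), n_truncate >= 0)
  bw <- acq_bandwidth(acq)
  f <- ppm_to_hz(group$lines$shift_ppm, acq)
  bad <- which(abs(f) >= bw / 2)
  if (length(bad))
    stop("line(s) outside +/- BW/2 for ", group$metabolite_name, ": ",
         paste(sprintf("%.2f ppm", group$lines$shift_ppm[bad]), collapse = ", "))
  t0 <- n_truncate / (bw * oversample)
  if (t0 >= acq$n_points * acq$dwell_time)
    stop("n_truncate removes the whole acquisition window")
  t <- acq_time_axis(acq) + t0
  x <- numeric(acq$n_points) + 0i
  for (l in seq_len(nrow(group$lines))) {
    x <- x + group$lines$rel_amp[l] *
      exp(2i * pi * f[l] * t) * exp(-t / group$t2_star)
  }
  fid_signal(x, acq)
}

#' Generate a synthetic macromolecule FID
#'
#' Sum of Gaussian-damped sinusoids
#' `A_j * exp(1i*phi_j) * exp(2i*pi*f_j*t) * exp(-beta_j*t^2)` with
#' `beta_j = (pi*FWHM_j)^2 / (4*ln 2)`, plus complex white Gaussian noise
#' with per-channel standard deviation `noise_sd`. Reproducible for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param truth Component table as returned by [default_mm_truth()].
#' @param acq An [acq_params()] object.
#' @param noise_sd Per-channel time-domain noise SD (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return An [fid_signal()].
#' @export
generate_mm_fid <- function(truth, acq = acq_nulled_7t(), noise_sd = 0, seed = 1) {
  stopifnot(noise_sd >= 0, nrow(truth) >= 1)
  x <- Reduce(`+`, component_fid_list(truth, acq))
  if (noise_sd > 0)
    x <- x + with_local_seed(seed, complex_noise(acq$n_points, noise_sd))
  fid_signal(x, acq)
}

#' Time-domain noise SD giving a target spectral SNR
#'
#' For an n-point DFT, white time-domain noise of per-channel SD `sigma`
#' produces spectral noise of per-channel SD `sigma*sqrt(n)`; with SNR
#' defined as peak height over twice the noise SD (as in [measure_peak()]),
#' the SD that yields SNR `snr` for a noiseless peak of height `h` is
#' `h / (2*snr*sqrt(n))`.
#'
#' @param fid_clean Noiseless [fid_signal()].
#' @param snr Target SNR of the tallest real-part peak in `window_ppm`.
#' @param window_ppm Window in which the reference peak is sought.
#' @return Per-channel time-domain noise SD.
#' @export
noise_sd_for_snr <- function(fid_clean, snr, window_ppm = c(0.2, 4.2)) {
  stopifnot(inherits(fid_clean, "fid_signal"), snr > 0)
  sp <- fid_to_spectrum(fid_clean)
  idx <- which(sp$ppm_axis >= min(window_ppm) & sp$ppm_axis <= max(window_ppm))
  h <- max(Re(sp$values[idx]))
  h / (2 * snr * sqrt(length(sp$values)))
}

#' Residual line positions left after metabolite nulling
#'
#' Chemical shifts of the metabolite residuals typically surviving double
#' inversion recovery nulling: NAA (2.01), myo-inositol (3.52), glutamate
#' (2.30), glutamine (2.45) and total creatine (3.98 ppm).
#' @return Named numeric vector.
#' @export
residual_positions <- function() {
  c(NAA = 2.01, Ins = 3.52, Glu = 2.30, Gln = 2.45, tCr = 3.98)
}

#' Generate a synthetic metabolite-nulled spectrum (MM + residuals)
#'
#' The MM FID of [generate_mm_fid()] plus five narrow Lorentzian residual
#' lines at the positions of [residual_positions()], each with amplitude
#' `residual_scale` relative to the MM1 amplitude. With
#' `residual_scale = 0` the output is identical to [generate_mm_fid()] for
#' the same seed.
#'
#' @param truth MM component table ([default_mm_truth()]).
#' @param residual_scale Residual amplitude as a fraction of MM1 (0-0.5).
#' @param acq An [acq_params()] object.
#' @param noise_sd Per-channel noise SD.
#' @param seed Integer seed.
#' @param residual_fwhm_hz Width of the residual lines (default 3 Hz,
#'   narrow compared to any MM peak; a 3 Hz Lorentzian keeps ~97% of its
#'   energy within 0.1 ppm of its center at 297 MHz).
#' @return An [fid_signal()].
#' @export
generate_metabolite_nulled_spectrum <- function(truth, residual_scale = 0.2,
                                                acq = acq_nulled_7t(),
                                                noise_sd = 0, seed = 1,
                                                residual_fwhm_hz = 3) {
  stopifnot(residual_scale >= 0, residual_scale <= 0.5)
  x <- Reduce(`+`, component_fid_list(truth, acq))
  if (residual_scale > 0) {
    a_mm1 <- truth$amplitude[match("MM1", truth$name)]
    if (is.na(a_mm1)) a_mm1 <- truth$amplitude[1]
    for (p in residual_positions()) {
      x <- x + component_fid_values(p, residual_fwhm_hz,
                                    residual_scale * a_mm1, 0,
                                    "lorentzian", acq)
    }
  }
  if (noise_sd > 0)
    x <- x + with_local_seed(seed, complex_noise(acq$n_points, noise_sd))
  fid_signal(x, acq)
}

#' Synthetic brain-slice tissue pattern
#'
#' Gray matter / white matter / cerebrospinal fluid probability maps on a
#' square grid: an elliptical brain mask with a cortical GM ribbon, interior
#' WM, a central CSF (ventricle) region, and a mild left-right GM gradient
#' so that the GM fraction spans a usable range. `"constant"` gives uniform
#' fractions inside the mask (useful for tests).
#'
#' @param n Matrix size.
#' @param pattern `"cortical"` (default) or `"constant"`.
#' @return List with matrices `f_gm`, `f_wm`, `f_csf` and logical `mask`.
#' @export
tissue_pattern <- function(n, pattern = c("cortical", "constant")) {
  pattern <- match.arg(pattern)
  xg <- matrix(rep(seq(-1, 1, length.out = n), each = n), n, n)
  yg <- t(xg)
  r <- sqrt((xg / 0.9)^2 + (yg / 0.9)^2)
  mask <- r <= 1
  f_gm <- matrix(0, n, n); f_wm <- matrix(0, n, n); f_csf <- matrix(0, n, n)
  if (pattern == "constant") {
    f_gm[mask] <- 0.4; f_wm[mask] <- 0.55; f_csf[mask] <- 0.05
  } else {
    gm <- exp(-((r - 0.72) / 0.20)^2) * (0.75 + 0.20 * xg)
    csf <- 0.85 * exp(-((sqrt(xg^2 + (yg / 0.6)^2)) / 0.18)^2)
    gm <- pmin(pmax(gm, 0), 0.95)
    csf <- pmin(pmax(csf, 0), 0.9)
    tot_rest <- pmax(1 - csf, 0)
    gm <- pmin(gm, tot_rest)
    f_gm[mask] <- gm[mask]
    f_csf[mask] <- csf[mask]
    f_wm[mask] <- (tot_rest - gm)[mask]
  }
  list(f_gm = f_gm, f_wm = f_wm, f_csf = f_csf, mask = mask)
}

#' Default per-component amplitude contrast rules for the phantom
#'
#' Maps every basis entry name to an `(intercept, gm_slope)` amplitude rule:
#' the true amplitude of component `c` in a voxel is
#' `intercept_c + gm_slope_c * gmf`, where `gmf = f_GM / (f_GM + f_WM)` is
#' the CSF-free gray-matter fraction. Metabolite levels follow the usual
#' qualitative 7T contrasts (Glu and tCr higher in GM); most MM components
#' rise with GM, MM7 is flat and MM8 falls (higher in WM).
#'
#' @param basis_names Character vector of basis entry names.
#' @param mm_truth MM truth table used to scale the MM rules.
#' @return Data frame with columns `name`, `intercept`, `gm_slope`.
#' @export
default_contrast_rules <- function(basis_names,
                                   mm_truth = default_mm_truth()) {
  met <- c(Glc = 1.5, Asp = 1.5, GPC = 0.8, PCh = 0.7, Cr = 4.0, PCr = 3.5,
           GABA = 1.0, Glu = 6.0, Gln = 2.0, GSH = 1.5, Gly = 0.6, Lac = 0.6,
           Ins = 4.0, NAA = 10.0, NAAG = 1.5, sIns = 0.4, Tau = 1.2)
  slope <- c(Glc = 0, Asp = 0, GPC = 0, PCh = 0, Cr = 1.5, PCr = 1.2,
             GABA = 0.4, Glu = 3.0, Gln = 0.8, GSH = 0, Gly = 0, Lac = 0,
             Ins = 1.0, NAA = 0, NAAG = -0.5, sIns = 0, Tau = 0.4)
  rules <- data.frame(name = basis_names, intercept = 0, gm_slope = 0,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rules))) {
    nm <- rules$name[i]
    if (nm %in% names(met)) {
      rules$intercept[i] <- met[[nm]]
      rules$gm_slope[i] <- slope[[nm]]
    } else if (nm %in% mm_truth$name) {
      a <- mm_truth$amplitude[match(nm, mm_truth$name)]
      # MM scale chosen so the MM background is prominent, as at short TE*
      rules$intercept[i] <- 2.0 * a
      rules$gm_slope[i] <- switch(nm, MM7 = 0, MM8 = -1.0 * a, 1.2 * a)
    } else {
      rules$intercept[i] <- 0  # e.g. lipid entries: rim-only, handled apart
    }
  }
  rules
}

#' Generate a 2D FID-MRSI phantom with ground truth
#'
#' Builds a square grid of synthetic FIDs: per voxel, basis entries scaled
#' by the contrast rules, an optional broad lipid pair (0.9 and 1.3 ppm) in
#' the outermost rim of the brain mask, a smooth left-right frequency
#' offset field, and complex white noise. Ground truth (amplitudes, tissue
#' fractions, offsets) is returned alongside.
#'
#' @param basis A [build_basis()] basis set providing the component FIDs.
#' @param matrix_size Square matrix size; must be a power of two (keeps
#'   k-space operations exact).
#' @param pattern Tissue pattern, see [tissue_pattern()].
#' @param contrast_rules Data frame `name`/`intercept`/`gm_slope`
#'   (default: [default_contrast_rules()]).
#' @param lipid_ring Add lipid contamination in the outermost 2-voxel rim
#'   of the mask (two Lorentzians at 0.9 and 1.3 ppm, FWHM 0.15 ppm, 10x
#'   the MM1 amplitude scale).
#' @param noise_sd Per-channel time-domain noise SD; alternatively give
#'   `target_snr`.
#' @param target_snr If non-`NULL`, sets `noise_sd` so the NAA peak of the
#'   noiseless voxel with the largest NAA amplitude has this spectral SNR.
#' @param freq_offset_hz Peak-to-peak amplitude of the linear left-right
#'   frequency offset field (Hz).
#' @param seed Integer seed.
#' @return List with `grid` (an [mrsi_grid()]) and `truth` (list with
#'   `amplitudes` voxel x component matrix, tissue maps, `mask`,
#'   `freq_offset`, `rules`, `seed`).
#' @export
generate_mrsi_phantom <- function(basis, matrix_size = 64,
                                  pattern = "cortical",
                                  contrast_rules = NULL,
                                  lipid_ring = TRUE,
                                  noise_sd = 0, target_snr = NULL,
                                  freq_offset_hz = 2, seed = 1) {
  stopifnot(inherits(basis, "basis_set"))
  if (matrix_size < 4 || bitwAnd(matrix_size, matrix_size - 1L) != 0)
    stop("matrix_size must be a power of two >= 4")
  acq <- basis$acq
  tis <- tissue_pattern(matrix_size, pattern)
  if (is.null(contrast_rules))
    contrast_rules <- default_contrast_rules(names(basis$entries))
  miss <- setdiff(contrast_rules$name, names(basis$entries))
  if (length(miss)) stop("contrast rule for unknown component: ",
                         paste(miss, collapse = ", "))
  gmf <- matrix(0, matrix_size, matrix_size)
  tot <- tis$f_gm + tis$f_wm
  gmf[tot > 0] <- tis$f_gm[tot > 0] / tot[tot > 0]

  nt <- acq$n_points
  t <- acq_time_axis(acq)
  B <- sapply(contrast_rules$name, function(nm) basis$entries[[nm]])  # nt x ncomp
  vox <- which(tis$mask, arr.ind = TRUE)
  amps <- matrix(0, nrow(vox), nrow(contrast_rules),
                 dimnames = list(NULL, contrast_rules$name))
  for (k in seq_len(nrow(vox))) {
    g <- gmf[vox[k, 1], vox[k, 2]]
    amps[k, ] <- contrast_rules$intercept + contrast_rules$gm_slope * g
  }
  amps[amps < 0] <- 0

  # outermost 2-voxel rim of the mask: voxels whose 5x5 neighborhood leaves it
  rim <- matrix(FALSE, matrix_size, matrix_size)
  for (k in seq_len(nrow(vox))) {
    i <- vox[k, 1]; j <- vox[k, 2]
    ii <- max(1, i - 2):min(matrix_size, i + 2)
    jj <- max(1, j - 2):min(matrix_size, j + 2)
    if (any(!tis$mask[ii, jj])) rim[i, j] <- TRUE
  }

  mm1_scale <- contrast_rules$intercept[match("MM1", contrast_rules$name)]
  if (is.na(mm1_scale) || mm1_scale <= 0) mm1_scale <- 1
  lipid_fid <- component_fid_values(0.9, 0.15 * acq$transmitter_frequency,
                                    10 * mm1_scale, 0, "lorentzian", acq) +
               component_fid_values(1.3, 0.15 * acq$transmitter_frequency,
                                    10 * mm1_scale, 0, "lorentzian", acq)

  xcoord <- seq(-1, 1, length.out = matrix_size)
  offs <- matrix(0, matrix_size, matrix_size)
  for (k in seq_len(nrow(vox)))
    offs[vox[k, 1], vox[k, 2]] <- freq_offset_hz / 2 * xcoord[vox[k, 1]]

  clean <- array(0i, dim = c(matrix_size, matrix_size, nt))
  for (k in seq_len(nrow(vox))) {
    i <- vox[k, 1]; j <- vox[k, 2]
    x <- as.vector(B %*% amps[k, ])
    if (lipid_ring && rim[i, j]) x <- x + lipid_fid
    if (offs[i, j] != 0) x <- x * exp(2i * pi * offs[i, j] * t)
    clean[i, j, ] <- x
  }

  if (!is.null(target_snr)) {
    k_ref <- which.max(amps[, "NAA"])
    ref_fid <- fid_signal(clean[vox[k_ref, 1], vox[k_ref, 2], ], acq)
    noise_sd <- noise_sd_for_snr(ref_fid, target_snr, window_ppm = c(1.9, 2.1))
  }
  fids <- clean
  if (noise_sd > 0) {
    noise <- with_local_seed(seed,
      complex(real = stats::rnorm(length(fids), sd = noise_sd),
              imaginary = stats::rnorm(length(fids), sd = noise_sd)))
    fids <- fids + array(noise, dim = dim(fids))
  }

  grid <- mrsi_grid(fids, mask = tis$mask, acq = acq,
                    f_gm = tis$f_gm, f_wm = tis$f_wm, f_csf = tis$f_csf)
  truth <- list(amplitudes = amps, voxels = vox, gmf = gmf,
                f_gm = tis$f_gm, f_wm = tis$f_wm, f_csf = tis$f_csf,
                mask = tis$mask, rim = rim, freq_offset = offs,
                rules = contrast_rules, noise_sd = noise_sd, seed = seed)
  list(grid = grid, truth = truth)
}
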