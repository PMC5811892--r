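#' Acquisition parameters for an FID-MRSI measurement
#'
#' Container for the timing and frequency metadata that every signal in the
#' package carries: dwell time, number of complex points, transmitter
#' frequency, the chemical shift assigned to zero frequency offset (water
#' reference), and optional sequence timings.
#'
#' @param dwell_time Seconds per complex point (> 0). The acquisition
#'   bandwidth is `1 / dwell_time`.
#' @param n_points Number of complex points (>= 2).
#' @param transmitter_frequency Transmitter (Larmor) frequency in MHz.
#'   Defaults to 297.22 MHz, i.e. protons at 7 T.
#' @param reference_ppm Chemical shift of zero frequency offset in ppm.
#'   Defaults to 4.7 ppm (water).
#' @param te_star Acquisition delay in seconds (optional).
#' @param tr Repetition time in seconds (optional).
#' @param ti1,ti2 Inversion times of a metabolite-nulling double inversion
#'   recovery protocol, seconds (metadata only).
#' @return An object of class `acq_params`.
#' @examples
#' acq <- acq_params(dwell_time = 1 / 6000, n_points = 2048)
#' acq_bandwidth(acq)
#' @export
acq_params <- function(dwell_time, n_points,
                       transmitter_frequency = 297.22,
                       reference_ppm = 4.7,
                       te_star = NULL, tr = NULL, ti1 = NULL, ti2 = NULL) {
  stopifnot(is.numeric(dwell_time), length(dwell_time) == 1L, dwell_time > 0)
  n_points <- as.integer(n_points)
  stopifnot(length(n_points) == 1L, n_points >= 2L)
  stopifnot(is.numeric(transmitter_frequency), transmitter_frequency > 0)
  structure(
    list(dwell_time = dwell_time,
         n_points = n_points,
         transmitter_frequency = transmitter_frequency,
         reference_ppm = reference_ppm,
         te_star = te_star, tr = tr, ti1 = ti1, ti2 = ti2),
    class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> %d pts, bw %.1f Hz, f0 %.2f MHz, ref %.2f ppm\n",
    x$n_points, acq_bandwidth(x), x$transmitter_frequency, x$reference_ppm))
  invisible(x)
}

#' Acquisition bandwidth in Hz
#' @param acq An `acq_params` object.
#' @return Bandwidth `1 / dwell_time` in Hz.
#' @export
acq_bandwidth <- function(acq) 1 / acq$dwell_time

#' Time axis of the FID in seconds
#' @param acq An `acq_params` object.
#' @return Numeric vector `0, dwell, 2*dwell, ...` of length `n_points`.
#' @export
acq_time_axis <- function(acq) (seq_len(acq$n_points) - 1) * acq$dwell_time

#' Convert frequency offset (Hz) to chemical shift (ppm) and back
#'
#' Chemical shift is `reference_ppm + offset_hz / transmitter_frequency`
#' with the transmitter frequency in MHz, so Hz/MHz gives ppm directly.
#'
#' @param hz,ppm Frequency offset in Hz / chemical shift in ppm.
#' @param acq An `acq_params` object.
#' @return Numeric vector of the converted values.
#' @export
hz_to_ppm <- function(hz, acq) acq$reference_ppm + hz / acq$transmitter_frequency

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(ppm, acq) (ppm - acq$reference_ppm) * acq$transmitter_frequency

#' Nominal in-plane voxel size of an MRSI protocol
#'
#' @param fov_mm In-plane field of view in mm.
#' @param matrix_size Encoding matrix size along the same direction.
#' @return Nominal voxel size `fov_mm / matrix_size` in mm.
#' @examples
#' nominal_voxel_size(220, 64)  # 3.4375 mm
#' nominal_voxel_size(180, 32)  # 5.625 mm
#' @export
nominal_voxel_size <- function(fov_mm, matrix_size) {
  stopifnot(fov_mm > 0, matrix_size >= 1)
  fov_mm / matrix_size
}

#' Standard acquisition protocols
#'
#' Convenience constructors for the two protocols used throughout the
#' package: the 64 x 64 water-suppressed FID-MRSI measurement and the
#' 32 x 32 double-inversion-recovery metabolite-nulled measurement. Both
#' sample 2,048 complex points at 6,000 Hz bandwidth with TE* = 1.3 ms.
#'
#' @return An `acq_params` object.
#' @export
acq_mrsi_7t <- function() {
  acq_params(dwell_time = 1 / 6000, n_points = 2048,
             transmitter_frequency = 297.22, reference_ppm = 4.7,
             te_star = 1.3e-3, tr = 0.600)
}

#' @rdname acq_mrsi_7t
#' @export
acq_nulled_7t <- function() {
  acq_params(dwell_time = 1 / 6000, n_points = 2048,
             transmitter_frequency = 297.22, reference_ppm = 4.7,
             te_star = 1.3e-3, tr = 0.879, ti1 = 0.570, ti2 = 0.021)
}
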