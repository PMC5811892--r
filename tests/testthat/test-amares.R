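test_that("a noiseless single Gaussian component is recovered exactly", {
  acq <- acq_short(512)
  truth <- data.frame(name = "G", center_ppm = 2.0, fwhm_hz = 18,
                      amplitude = 1.3, phase_deg = 0, lineshape = "gaussian")
  fid <- generate_mm_fid(truth, acq)
  # prior deliberately off-center by 0.05 ppm
  pri <- peak_priors("G", 2.05, center_delta = 0.1, fwhm_init = 25,
                     fwhm_lo = 5, fwhm_hi = 50)
  fit <- amares_fit(fid, pri)
  expect_true(fit$converged)
  expect_equal(fit$components$center_ppm, 2.0, tolerance = 1e-6)
  expect_equal(fit$components$fwhm_hz, 18, tolerance = 1e-4)
  expect_equal(fit$components$amplitude, 1.3, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("nine-component fit recovers the MM truth at SNR 50", {
  acq <- acq_nulled_7t()
  truth <- default_mm_truth(acq)
  nsd <- noise_sd_for_snr(generate_mm_fid(truth, acq), 50)
  cen_err <- amp_err <- NULL
  for (s in 1:5) {
    fid <- generate_mm_fid(truth, acq, noise_sd = nsd, seed = s)
    m <- parameterize_mm_amares(fid)
    expect_length(m$fids, 9)
    cen_err <- c(cen_err, abs(m$components$center_ppm - truth$center_ppm))
    amp_err <- c(amp_err, abs(m$components$amplitude / truth$amplitude - 1))
  }
  expect_lt(max(cen_err), 0.02)
  expect_lt(max(amp_err), 0.10)
})

test_that("the fit residual reaches the noise floor at SNR 50", {
  acq <- acq_nulled_7t()
  truth <- default_mm_truth(acq)
  nsd <- noise_sd_for_snr(generate_mm_fid(truth, acq), 50)
  fid <- generate_mm_fid(truth, acq, noise_sd = nsd, seed = 3)
  fit <- amares_fit(fid, default_mm_priors())
  expect_lt(fit$residual_rms, 1.5 * nsd)
  expect_true(all(fit$components$center_ppm <= 4.2))
})

test_that("estimator RMSE shrinks as SNR doubles", {
  acq <- acq_params(1 / 6000, 1024)
  truth <- mini_mm_truth(acq)
  pri <- peak_priors(truth$name, truth$center_ppm, center_delta = 0.08,
                     fwhm_init = 18, fwhm_lo = 5, fwhm_hi = 40)
  base_fid <- generate_mm_fid(truth, acq)
  rmse <- sapply(c(12.5, 25, 50, 100), function(snr) {
    nsd <- noise_sd_for_snr(base_fid, snr)
    errs <- sapply(1:6, function(s) {
      fit <- amares_fit(generate_mm_fid(truth, acq, nsd, seed = s), pri)
      mean((fit$components$amplitude - truth$amplitude)^2)
    })
    sqrt(mean(errs))
  })
  # monotone within Monte-Carlo error: allow one small inversion of 20%
  expect_true(sum(diff(rmse) > 0.2 * rmse[-4]) == 0)
  expect_lt(rmse[4], rmse[1])
})

test_that("Lorentzian-prior fit matches the Hankel-SVD estimate", {
  acq <- acq_short(512)
  fid <- damped_fid(acq, ppm_to_hz(2.5, acq), 25, amp = 0.9, phase = 0.3)
  h <- hlsvd_decompose(fid, 1)
  pri <- peak_priors("L", 2.45, center_delta = 0.15, fwhm_init = 10,
                     fwhm_lo = 2, fwhm_hi = 40, lineshape = "lorentzian")
  a <- amares_fit(fid, pri)
  expect_equal(a$components$center_ppm,
               hz_to_ppm(h$frequency_hz, acq), tolerance = 1e-4)
  expect_equal(a$components$fwhm_hz, h$damping_s / pi, tolerance = 1e-4)
  expect_equal(a$components$amplitude, h$amplitude, tolerance = 1e-4)
  expect_equal(a$components$phase_deg * pi / 180, h$phase_rad, tolerance = 1e-4)
})

test_that("CRLB from Fisher information matches Monte-Carlo spread", {
  acq <- acq_params(1 / 6000, 1024)
  truth <- mini_mm_truth(acq)
  pri <- peak_priors(truth$name, truth$center_ppm, center_delta = 0.08,
                     fwhm_init = 18, fwhm_lo = 5, fwhm_hi = 40)
  nsd <- noise_sd_for_snr(generate_mm_fid(truth, acq), 30)
  amps <- crlbs <- NULL
  for (s in 1:60) {
    fit <- amares_fit(generate_mm_fid(truth, acq, nsd, seed = 400 + s), pri)
    amps <- rbind(amps, fit$components$amplitude)
    crlbs <- rbind(crlbs, fit$components$crlb_amp_pct)
  }
  emp_pct <- 100 * apply(amps, 2, sd) / colMeans(amps)
  rep_pct <- colMeans(crlbs)
  expect_true(all(abs(emp_pct / rep_pct - 1) < 0.35))
})

test_that("metabolite residual removal cleans the five lines, preserves MM", {
  acq <- acq_nulled_7t()
  truth <- default_mm_truth(acq)
  clean <- generate_metabolite_nulled_spectrum(truth, 0, acq)
  with_res <- generate_metabolite_nulled_spectrum(truth, 0.3, acq)

  # residual-free input passes through (joint refit changes nothing);
  # the fitter warns that the residual amplitudes pinned at zero
  out0 <- suppressWarnings(remove_metabolite_residuals(clean))
  expect_lt(max(Mod(out0$samples - clean$samples)) / max(Mod(clean$samples)),
            5e-3)

  out <- remove_metabolite_residuals(with_res)
  sp_before <- fid_to_spectrum(with_res)
  sp_after <- fid_to_spectrum(out)
  sp_clean <- fid_to_spectrum(clean)
  # energy added by the residual lines is removed almost completely
  win <- rep(FALSE, length(sp_clean$ppm_axis))
  for (p in residual_positions())
    win <- win | abs(sp_clean$ppm_axis - p) <= 0.05
  e_before <- sum(Mod(sp_before$values[win] - sp_clean$values[win])^2)
  e_after <- sum(Mod(sp_after$values[win] - sp_clean$values[win])^2)
  expect_lt(e_after / e_before, 0.1)
  # MM-window energy (0.8-1.8 ppm) essentially untouched
  mm_win <- sp_clean$ppm_axis >= 0.8 & sp_clean$ppm_axis <= 1.8
  e_mm_before <- sum(Mod(sp_before$values[mm_win])^2)
  e_mm_after <- sum(Mod(sp_after$values[mm_win])^2)
  expect_lt(abs(e_mm_after / e_mm_before - 1), 0.02)
})

test_that("priors table validation and TSV round trip", {
  expect_error(peak_priors("A", 2.0, center_lo = 2.1, center_hi = 2.2),
               "degenerate")
  pri <- default_mm_priors()
  expect_equal(nrow(pri), 9)
  path <- tempfile(fileext = ".tsv")
  write_priors_tsv(pri, path)
  back <- read_priors_tsv(path)
  expect_equal(back$center_init, pri$center_init)
  expect_equal(back$fwhm_hi, pri$fwhm_hi)
  unlink(path)
})
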