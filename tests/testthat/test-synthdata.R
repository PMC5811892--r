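test_that("metabolite simulation: constant FID for an on-resonance line", {
  acq <- acq_short(256)
  g <- line_group("X", 4.7, 2, t2_star = 1e9)
  fid <- simulate_metabolite_fid(g, acq, n_truncate = 0)
  expect_equal(Mod(fid$samples), rep(2, 256), tolerance = 1e-6)
})

test_that("metabolite simulation rejects out-of-bandwidth lines", {
  acq <- acq_short(256)
  g <- line_group("far", 4.7 + 4000 / acq$transmitter_frequency, 1)
  expect_error(simulate_metabolite_fid(g, acq), "outside")
})

test_that("truncated simulation carries the acquisition-delay phase ramp", {
  acq <- acq_params(1 / 6000, 2048)
  g <- line_group("NAAacetyl", 2.01, 3, t2_star = 0.08)
  fid <- simulate_metabolite_fid(g, acq, n_truncate = 39, oversample = 5)
  # 39 points at 30 kHz = 1.3 ms delay; re-phasing with the time-shift
  # slope must give an absorptive peak at 2.01 ppm
  tau_points_native <- 39 / 5
  sp <- phase_correct(fid_to_spectrum(fid), 0,
                      delay_phase_per_ppm(tau_points_native, acq))
  pm <- measure_peak(sp, c(1.8, 2.2))
  expect_equal(pm$center_ppm, 2.01, tolerance = 0.01)
  i0 <- which.max(Re(sp$values))
  asym <- Im(sp$values[(i0 - 8):(i0 - 1)]) + rev(Im(sp$values[(i0 + 1):(i0 + 8)]))
  expect_lt(max(abs(asym)) / max(Re(sp$values)), 0.1)
})

test_that("the default metabolite panel has 17 groups and in-window lines", {
  groups <- metabolite_line_groups()
  expect_length(groups, 17)
  acq <- acq_params(1 / 6000, 2048)
  fids <- lapply(groups, simulate_metabolite_fid, acq = acq)
  expect_length(fids, 17)
  for (g in groups)
    expect_true(all(g$lines$shift_ppm >= 0.2 & g$lines$shift_ppm <= 4.2))
})

test_that("MM generator is deterministic and linear in amplitude", {
  acq <- acq_short(512)
  truth <- mini_mm_truth(acq)
  a <- generate_mm_fid(truth, acq, noise_sd = 0.01, seed = 9)
  b <- generate_mm_fid(truth, acq, noise_sd = 0.01, seed = 9)
  expect_identical(a$samples, b$samples)
  c2 <- generate_mm_fid(truth, acq, noise_sd = 0.01, seed = 10)
  expect_false(identical(a$samples, c2$samples))

  # single noiseless component peaks at its center within a bin
  one <- truth[1, ]
  sp <- fid_to_spectrum(generate_mm_fid(one, acq))
  bin <- 6000 / 512 / acq$transmitter_frequency
  expect_lt(abs(sp$ppm_axis[which.max(Re(sp$values))] - 1.0), bin)

  # integrated real spectrum scales linearly with the amplitude
  areas <- sapply(c(0.5, 1, 2, 4), function(aa) {
    one$amplitude <- aa
    spp <- fid_to_spectrum(generate_mm_fid(one, acq))
    idx <- spp$ppm_axis > 0.5 & spp$ppm_axis < 1.5
    sum(Re(spp$values[idx]))
  })
  fitl <- lm(areas ~ c(0.5, 1, 2, 4))
  expect_lt(abs(coef(fitl)[1]) / areas[2], 0.01)            # no offset
  expect_equal(areas[3] / areas[2], 2, tolerance = 0.01)    # slope exact
})

test_that("nulled-spectrum generator adds residuals only at the five positions", {
  acq <- acq_params(1 / 6000, 2048)
  truth <- default_mm_truth(acq)
  base <- generate_metabolite_nulled_spectrum(truth, 0, acq, noise_sd = 0.01,
                                              seed = 4)
  ref <- generate_mm_fid(truth, acq, noise_sd = 0.01, seed = 4)
  expect_identical(base$samples, ref$samples)

  with_res <- generate_metabolite_nulled_spectrum(truth, 0.3, acq)
  clean <- generate_metabolite_nulled_spectrum(truth, 0, acq)
  sp_r <- fid_to_spectrum(with_res); sp_c <- fid_to_spectrum(clean)
  # residual peaks appear at the printed metabolite positions
  for (p in residual_positions()) {
    diffspec <- Re(sp_r$values) - Re(sp_c$values)
    idx <- which(abs(sp_r$ppm_axis - p) < 0.05)
    pk <- sp_r$ppm_axis[idx[which.max(diffspec[idx])]]
    expect_lt(abs(pk - p), 0.01)
  }
  # >95% of the added energy lies within 0.1 ppm of the five positions
  dE <- (Re(sp_r$values) - Re(sp_c$values))^2 +
    (Im(sp_r$values) - Im(sp_c$values))^2
  near <- rep(FALSE, length(dE))
  for (p in residual_positions())
    near <- near | abs(sp_r$ppm_axis - p) <= 0.1
  expect_gt(sum(dE[near]) / sum(dE), 0.95)
})

test_that("phantom generator: constant tissue and no noise give identical voxels", {
  acq <- acq_short(256)
  basis <- mini_basis(acq)
  rules <- data.frame(name = c("A", "B", "C"), intercept = c(1, 2, 3),
                      gm_slope = 0)
  ph <- generate_mrsi_phantom(basis, matrix_size = 8, pattern = "constant",
                              contrast_rules = rules, lipid_ring = FALSE,
                              noise_sd = 0, freq_offset_hz = 0, seed = 1)
  vox <- ph$truth$voxels
  ref <- ph$grid$fids[vox[1, 1], vox[1, 2], ]
  for (k in seq_len(nrow(vox)))
    expect_equal(ph$grid$fids[vox[k, 1], vox[k, 2], ], ref)
  expect_error(generate_mrsi_phantom(basis, matrix_size = 12), "power of two")
})

test_that("phantom truth amplitudes follow the configured GM-slope rule exactly", {
  acq <- acq_short(256)
  basis <- mini_basis(acq)
  rules <- data.frame(name = c("A", "B", "C"), intercept = c(1, 2, 3),
                      gm_slope = c(2, 0, -1))
  ph <- generate_mrsi_phantom(basis, matrix_size = 16, pattern = "cortical",
                              contrast_rules = rules, lipid_ring = FALSE,
                              noise_sd = 0, seed = 1)
  vox <- ph$truth$voxels
  gmf <- ph$truth$gmf[vox]
  expect_equal(ph$truth$amplitudes[, "A"], pmax(1 + 2 * gmf, 0))
  expect_equal(ph$truth$amplitudes[, "C"], pmax(3 - gmf, 0))
  # noiseless regression of truth on gmf returns the slope exactly
  fitl <- lm(ph$truth$amplitudes[, "A"] ~ gmf)
  expect_equal(unname(coef(fitl)[2]), 2, tolerance = 1e-9)
})

test_that("default 64x64 phantom has 4096 voxels with a usable brain mask", {
  tis <- tissue_pattern(64)
  expect_equal(length(tis$mask), 4096)
  expect_gt(mean(tis$mask), 0.6)
  s <- tis$f_gm + tis$f_wm + tis$f_csf
  expect_true(all(s <= 1.0001))
  expect_true(all(s[tis$mask] > 0.99))
})
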