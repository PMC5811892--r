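# Small grids keep these tests fast; the full 32x32 protocol runs in the
# acceptance suite.

small_grid_fixture <- function(noise_sd = 0, matrix_size = 8) {
  acq <- acq_params(1 / 6000, 512)
  basis <- mini_basis(acq)
  rules <- data.frame(name = c("A", "B", "C"), intercept = c(2, 3, 1),
                      gm_slope = c(1, 0, -0.5))
  ph <- generate_mrsi_phantom(basis, matrix_size = matrix_size,
                              pattern = "cortical", contrast_rules = rules,
                              lipid_ring = FALSE, noise_sd = noise_sd,
                              freq_offset_hz = 0, seed = 3)
  list(ph = ph, basis = basis, rules = rules)
}

test_that("noiseless grid quantification recovers every voxel", {
  fx <- small_grid_fixture()
  # peak B sits at 2.0 ppm: reuse it as the reliability reference
  opts <- lc_fit_options(naa_window = c(1.9, 2.1))
  fit <- quantify_grid(fx$ph$grid, fx$basis, opts)
  expect_false(any(fit$failed))
  key <- paste(fx$ph$truth$voxels[, 1], fx$ph$truth$voxels[, 2])
  m <- match(paste(fit$voxels[, 1], fit$voxels[, 2]), key)
  for (comp in c("A", "B", "C")) {
    relerr <- abs(fit$amplitudes[, comp] - fx$ph$truth$amplitudes[m, comp]) /
      pmax(fx$ph$truth$amplitudes[m, comp], 1e-9)
    expect_lt(max(relerr), 0.01)
  }
})

test_that("evaluation order does not matter and masked voxels are skipped", {
  fx <- small_grid_fixture()
  opts <- lc_fit_options(naa_window = c(1.9, 2.1))
  fit1 <- quantify_grid(fx$ph$grid, fx$basis, opts)
  # permute the mask scan order by transposing the grid contents
  g2 <- fx$ph$grid
  g2$fids <- aperm(g2$fids, c(2, 1, 3))
  g2$mask <- t(g2$mask)
  g2$f_gm <- t(g2$f_gm); g2$f_wm <- t(g2$f_wm); g2$f_csf <- t(g2$f_csf)
  fit2 <- quantify_grid(g2, fx$basis, opts)
  k1 <- order(fit1$voxels[, 1], fit1$voxels[, 2])
  k2 <- order(fit2$voxels[, 2], fit2$voxels[, 1])
  expect_equal(fit1$amplitudes[k1, "A"], fit2$amplitudes[k2, "A"],
               tolerance = 1e-10)
  # voxels outside the mask produce no result rows
  expect_equal(nrow(fit1$voxels), sum(fx$ph$grid$mask))
})

test_that("QA filter applies the conjunctive rule with strict inequalities", {
  fx <- small_grid_fixture()
  opts <- lc_fit_options(naa_window = c(1.9, 2.1))
  fit <- quantify_grid(fx$ph$grid, fx$basis, opts)
  n <- nrow(fit$voxels)
  # construct the QA inputs by hand
  fit$crlb_naa <- rep(10, n); fit$fwhm_naa <- rep(10, n)
  fit$crlb_naa[1] <- 35; fit$fwhm_naa[1] <- 25   # both fail -> auto
  fit$crlb_naa[2] <- 35; fit$fwhm_naa[2] <- 15   # one fails -> flagged
  fit$crlb_naa[3] <- 10; fit$fwhm_naa[3] <- 25   # one fails -> flagged
  fit$crlb_naa[4] <- 30; fit$fwhm_naa[4] <- 20   # exactly at limits -> kept
  qa <- qa_filter(fit)
  expect_true(qa$excluded[1]); expect_equal(qa$reason[1], "auto")
  expect_false(qa$excluded[2])
  expect_equal(qa$reason[2], "flagged_single_criterion")
  expect_false(qa$excluded[3])
  expect_equal(qa$reason[3], "flagged_single_criterion")
  expect_false(qa$excluded[4]); expect_equal(qa$reason[4], "none")
  expect_true(all(qa$reason[qa$excluded] != "none"))
  # monotonicity: lowering either limit never un-excludes
  qa2 <- qa_filter(fit, fwhm_limit = 10, crlb_limit = 10)
  expect_true(all(qa2$excluded[qa$excluded]))
})

test_that("component maps honor mask, QA and the CRLB display threshold", {
  fx <- small_grid_fixture()
  opts <- lc_fit_options(naa_window = c(1.9, 2.1))
  fit <- quantify_grid(fx$ph$grid, fx$basis, opts)
  qa <- qa_filter(fit)
  mp <- make_map(fit, qa, "A")
  expect_true(all(is.na(mp[!fx$ph$grid$mask])))
  key <- paste(fx$ph$truth$voxels[, 1], fx$ph$truth$voxels[, 2])
  m <- match(paste(fit$voxels[, 1], fit$voxels[, 2]), key)
  defined <- !is.na(mp[fit$voxels])
  expect_gt(sum(defined), 0)
  expect_lt(max(abs(mp[fit$voxels][defined] -
                    fx$ph$truth$amplitudes[m, "A"][defined]) /
              fx$ph$truth$amplitudes[m, "A"][defined]), 0.01)
  expect_error(make_map(fit, qa, "nope"), "unknown")
  # all-excluded grid gives a fully undefined map
  qa_all <- qa; qa_all$excluded[] <- TRUE
  expect_true(all(is.na(make_map(fit, qa_all, "A"))))
  # threshold 0: only exact-zero CRLB voxels survive
  mp0 <- make_map(fit, qa, "A", crlb_threshold = 0)
  shown <- !is.na(mp0[fit$voxels])
  expect_true(all(fit$crlb_percent[shown, "A"] == 0))
})

test_that("k-space tissue downsampling preserves DC and complements", {
  n <- 64; tm <- 16
  const <- matrix(0.7, n, n)
  out <- downsample_tissue_maps(list(gm = const), tm)
  expect_equal(out$gm, matrix(0.7, tm, tm), tolerance = 1e-9)

  set.seed(12)
  f <- matrix(runif(n * n), n, n)
  pair <- downsample_tissue_maps(list(a = f, b = 1 - f), tm)
  pre <- attr(pair, "pre_clip")
  expect_equal(pre$a + pre$b, matrix(1, tm, tm), tolerance = 1e-6)
  # DC (image mean) preserved before clipping
  expect_equal(mean(pre$a), mean(f), tolerance = 1e-6)

  expect_error(downsample_tissue_maps(list(bad = f * 3), tm),
               "non-probability")
})

test_that("downsampling a half-plane step shows ringing but correct means", {
  n <- 64; tm <- 16
  step <- matrix(0, n, n); step[, (n / 2 + 1):n] <- 1
  pre <- attr(downsample_tissue_maps(list(s = step), tm), "pre_clip")$s
  # means taken away from the two transitions (center and circular wrap)
  left <- pre[, 2:(tm / 2 - 1)]; right <- pre[, (tm / 2 + 2):(tm - 1)]
  expect_lt(abs(mean(left) - 0), 0.02)
  expect_lt(abs(mean(right) - 1), 0.02)
  # Gibbs ringing exists in the pre-clip image
  expect_gt(max(pre), 1)

  # elliptical k-space mask averages slightly differently but stays close
  oute <- downsample_tissue_maps(list(s = step), tm, elliptical_k = TRUE)$s
  expect_lt(abs(mean(oute) - 0.5), 0.02)
})

test_that("GM-fraction regression recovers the construction slope", {
  fx <- small_grid_fixture(matrix_size = 16)
  opts <- lc_fit_options(naa_window = c(1.9, 2.1))
  fit <- quantify_grid(fx$ph$grid, fx$basis, opts)
  qa <- qa_filter(fit)
  reg <- gm_fraction_regression(make_map(fit, qa, "A"), fx$ph$grid)
  expect_equal(reg$slope, 1, tolerance = 1e-3)
  regC <- gm_fraction_regression(make_map(fit, qa, "C"), fx$ph$grid)
  expect_equal(regC$slope, -0.5, tolerance = 1e-3)
  # degenerate input: constant tissue has no GM-fraction variation
  fx2 <- small_grid_fixture(matrix_size = 8)
  g <- fx2$ph$grid
  g$f_gm <- 0.4 * g$mask; g$f_wm <- 0.6 * g$mask
  g$f_csf <- matrix(0, 8, 8)
  fit2 <- quantify_grid(g, fx2$basis, opts)
  qa2 <- qa_filter(fit2)
  expect_error(gm_fraction_regression(make_map(fit2, qa2, "A"), g),
               "degenerate|insufficient")
})

test_that("NIfTI round trip of tissue maps", {
  tis <- tissue_pattern(16)
  path <- tempfile(fileext = ".nii.gz")
  write_maps_nifti(list(gm = tis$f_gm, wm = tis$f_wm, csf = tis$f_csf), path)
  back <- read_tissue_nifti(path)
  expect_equal(back$gm, tis$f_gm, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$csf, tis$f_csf, tolerance = 1e-6, ignore_attr = TRUE)
  unlink(path)
})

test_that("FID text format round-trips with metadata", {
  acq <- acq_params(1 / 6000, 64, transmitter_frequency = 297.22)
  set.seed(8)
  fid <- fid_signal(complex(real = rnorm(64), imaginary = rnorm(64)), acq)
  path <- tempfile(fileext = ".txt")
  write_fid_text(fid, path)
  back <- read_fid_text(path)
  expect_equal(back$samples, fid$samples)
  expect_equal(back$acq$dwell_time, acq$dwell_time)
  expect_equal(back$acq$transmitter_frequency, acq$transmitter_frequency)
  unlink(path)
})
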