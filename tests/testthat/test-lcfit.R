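# Small acquisition (1,024 pts) keeps each fit around 50 ms; the
# full-length protocol runs in the acceptance suite.

lc_acq <- function() acq_params(1 / 6000, 1024)

lc_fixture <- function(acq = lc_acq(), with_priors = FALSE) {
  truth <- default_mm_truth(acq)
  mm <- mm_model_from_components(truth, acq, "AMARES")
  if (with_priors) {
    rp <- data.frame(numerator = paste0("MM", 2:9),
                     expected_ratio = truth$amplitude[2:9] / truth$amplitude[1],
                     sd = 0.1 * truth$amplitude[2:9] / truth$amplitude[1],
                     stringsAsFactors = FALSE)
    attr(rp, "denominator") <- "MM1"
    class(rp) <- c("ratio_priors", "data.frame")
    mm <- mm_model_with_priors(mm, rp)
  }
  basis <- build_basis(metabolite_line_groups(), mm, acq)
  rules <- default_contrast_rules(names(basis$entries))
  amps <- structure(pmax(rules$intercept + rules$gm_slope * 0.5, 0),
                    names = rules$name)
  fid <- fid_signal(as.vector(sapply(basis$entries, identity) %*% amps), acq)
  list(basis = basis, amps = amps, fid = fid, truth = truth)
}

test_that("noiseless realizable spectra are recovered almost exactly", {
  fx <- lc_fixture()
  # 5 well-separated entries only: unambiguous amplitudes
  sub <- fx$basis
  keep <- c("NAA", "Cr", "Ins", "MM1", "MM9")
  sub$entries <- sub$entries[keep]
  sub$metabolite_names <- intersect(sub$metabolite_names, keep)
  sub$mm_names <- intersect(sub$mm_names, keep)
  a_true <- c(NAA = 10, Cr = 5, Ins = 4, MM1 = 2, MM9 = 1.5)
  fid <- fid_signal(as.vector(sapply(sub$entries, identity) %*% a_true),
                    sub$acq)
  res <- lc_fit(fid, sub)
  expect_true(res$converged)
  expect_equal(unname(res$amplitudes[keep] / a_true), rep(1, 5),
               tolerance = 1e-4)
  expect_lt(max(abs(res$baseline)), 1e-3 * max(abs(res$fitted)))
  expect_lt(max(res$crlb_percent[keep]), 0.1)
})

test_that("amplitudes equal the NNLS oracle when nonlinears are frozen", {
  fx <- lc_fixture()
  opts <- lc_fit_options(optimize_phase = FALSE, optimize_shift = FALSE,
                         optimize_broadening = FALSE,
                         baseline_knot_spacing = NULL)
  res <- lc_fit(fx$fid, fx$basis, opts)
  # oracle: pracma's non-negative least squares on the same design
  sp <- fid_to_spectrum(fx$fid)
  idx <- which(sp$ppm_axis >= 0.2 & sp$ppm_axis <= 4.2)
  C <- sapply(fx$basis$entries, function(e)
    Re(fid_to_spectrum(fid_signal(e, fx$basis$acq))$values[idx]))
  oracle <- pracma::lsqnonneg(C, Re(sp$values[idx]))$x
  expect_equal(unname(res$amplitudes), oracle, tolerance = 1e-8)
})

test_that("fit is equivariant under overall scaling, CRLB% invariant", {
  fx <- lc_fixture()
  set.seed(77)
  nsd <- noise_sd_for_snr(fx$fid, 40, c(1.9, 2.1))
  noisy <- fx$fid$samples +
    complex(real = rnorm(1024, sd = nsd), imaginary = rnorm(1024, sd = nsd))
  r1 <- lc_fit(fid_signal(noisy, fx$basis$acq), fx$basis)
  r2 <- lc_fit(fid_signal(5 * noisy, fx$basis$acq), fx$basis)
  expect_equal(unname(r2$amplitudes / pmax(r1$amplitudes, 1e-12))[r1$amplitudes > 0.1],
               rep(5, sum(r1$amplitudes > 0.1)), tolerance = 1e-2)
  big <- r1$amplitudes > 0.5
  expect_equal(r2$crlb_percent[big], r1$crlb_percent[big], tolerance = 0.05)
})

test_that("phase, shift and broadening applied to the data are recovered", {
  fx <- lc_fixture()
  acq <- fx$basis$acq
  t <- acq_time_axis(acq)
  distorted <- fx$fid$samples * exp(2i * pi * 2 * t) *
    exp(-(pi * 3)^2 / (4 * log(2)) * t^2) * exp(1i * 10 * pi / 180)
  res <- lc_fit(fid_signal(distorted, acq), fx$basis)
  expect_equal(res$global_shift_ppm, 2 / acq$transmitter_frequency,
               tolerance = 2e-3)
  expect_equal(res$broadening_hz, 3, tolerance = 0.3)
  expect_equal(res$phi0, -10, tolerance = 1)
  expect_equal(unname(res$amplitudes["NAA"] / fx$amps["NAA"]), 1,
               tolerance = 0.02)
})

test_that("infinite prior weight drives ratios to their prior values", {
  fx <- lc_fixture(with_priors = TRUE)
  set.seed(5)
  nsd <- noise_sd_for_snr(fx$fid, 40, c(1.9, 2.1))
  noisy <- fid_signal(fx$fid$samples +
    complex(real = rnorm(1024, sd = nsd), imaginary = rnorm(1024, sd = nsd)),
    fx$basis$acq)
  res <- lc_fit(noisy, fx$basis, lc_fit_options(ratio_prior_weight = 1e8))
  rp <- fx$basis$ratio_priors
  fitted_ratio <- res$amplitudes[rp$numerator] / res$amplitudes["MM1"]
  expect_equal(unname(fitted_ratio), rp$expected_ratio, tolerance = 0.01)
})

test_that("ratio priors shrink MM variability without biasing NAA", {
  fx_c <- lc_fixture(with_priors = TRUE)
  fx_i <- lc_fixture(with_priors = FALSE)
  nsd <- noise_sd_for_snr(fx_c$fid, 40, c(1.9, 2.1))
  acq <- fx_c$basis$acq
  a_c <- a_i <- NULL
  for (s in 1:12) {
    set.seed(s)
    noisy <- fid_signal(fx_c$fid$samples +
      complex(real = rnorm(1024, sd = nsd), imaginary = rnorm(1024, sd = nsd)),
      acq)
    a_c <- rbind(a_c, lc_fit(noisy, fx_c$basis)$amplitudes[c("NAA", "MM2")])
    a_i <- rbind(a_i, lc_fit(noisy, fx_i$basis)$amplitudes[c("NAA", "MM2")])
  }
  expect_lt(sd(a_c[, "MM2"]), sd(a_i[, "MM2"]))
  expect_lt(abs(mean(a_c[, "NAA"]) / fx_c$amps["NAA"] - 1), 0.05)
  expect_lt(abs(mean(a_i[, "NAA"]) / fx_i$amps["NAA"] - 1), 0.05)
})

test_that("CRLB: near zero noiseless, scales with noise, 999 sentinel", {
  fx <- lc_fixture()
  res0 <- lc_fit(fx$fid, fx$basis)
  expect_lt(res0$crlb_percent["NAA"], 0.1)

  nsd <- noise_sd_for_snr(fx$fid, 40, c(1.9, 2.1))
  crlb_at <- function(scale, seeds) sapply(seeds, function(s) {
    set.seed(s)
    noisy <- fid_signal(fx$fid$samples + complex(
      real = rnorm(1024, sd = scale * nsd),
      imaginary = rnorm(1024, sd = scale * nsd)), fx$basis$acq)
    lc_fit(noisy, fx$basis)$crlb_percent["NAA"]
  })
  hi <- mean(crlb_at(1, 1:4)); lo <- mean(crlb_at(0.5, 1:4))
  expect_equal(hi / lo, 2, tolerance = 0.3)

  # an absent component reports the sentinel
  sub <- fx$basis
  a_true <- c(NAA = 10, Cr = 5, Ins = 0)
  keep <- names(a_true)
  sub$entries <- sub$entries[keep]
  sub$metabolite_names <- keep; sub$mm_names <- character(0)
  set.seed(2)
  fid <- fid_signal(as.vector(sapply(sub$entries, identity) %*% a_true) +
    complex(real = rnorm(1024, sd = nsd), imaginary = rnorm(1024, sd = nsd)),
    sub$acq)
  res <- lc_fit(fid, sub)
  expect_equal(unname(res$crlb_percent["Ins"]), 999)
})

test_that("lipid entries in the basis improve a contaminated-voxel fit", {
  acq <- lc_acq()
  fx <- lc_fixture(acq)
  t <- acq_time_axis(acq)
  lip <- 20 * exp(2i * pi * ppm_to_hz(0.9, acq) * t - pi * 0.15 *
                    acq$transmitter_frequency * t) +
         20 * exp(2i * pi * ppm_to_hz(1.3, acq) * t - pi * 0.15 *
                    acq$transmitter_frequency * t)
  contaminated <- fid_signal(fx$fid$samples + lip, acq)
  plain <- lc_fit(contaminated, fx$basis)
  with_lip <- lc_fit(contaminated, add_simulated_lipids(fx$basis))
  expect_lt(with_lip$objective, plain$objective)
  expect_gt(plain$lipid_area_ratio, 1 / 3)   # flagged by the lipid screen
  expect_lt(lc_fit(fx$fid, fx$basis)$lipid_area_ratio, 1 / 3)
})
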