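# Shared fixtures: short acquisitions keep the unit tests fast; the
# full-length 2,048-point protocol is exercised in the acceptance tests.

acq_short <- function(n = 512) acq_params(1 / 6000, n)

# single damped sinusoid on the acquisition grid
damped_fid <- function(acq, f_hz, damp_s, amp = 1, phase = 0) {
  t <- acq_time_axis(acq)
  fid_signal(amp * exp(1i * phase) * exp((2i * pi * f_hz - damp_s) * t), acq)
}

# small three-peak truth for fast parameterization tests
mini_mm_truth <- function(acq) {
  data.frame(name = c("P1", "P2", "P3"),
             center_ppm = c(1.0, 2.0, 3.0),
             fwhm_hz = c(12, 20, 16),
             amplitude = c(1.0, 0.6, 0.8),
             phase_deg = 0, lineshape = "gaussian",
             stringsAsFactors = FALSE)
}

# reproducible complex noise vector
with_seed_noise <- function(seed, n, sd) {
  set.seed(seed)
  complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd))
}

# tiny synthetic basis: three well separated Lorentzian singlets
mini_basis <- function(acq, t2 = 0.08) {
  groups <- list(A = line_group("A", 1.0, 1, t2),
                 B = line_group("B", 2.0, 1, t2),
                 C = line_group("C", 3.0, 1, t2))
  ent <- lapply(groups, function(g)
    simulate_metabolite_fid(g, acq, n_truncate = 0)$samples)
  basis_set(ent, acq, metabolite_names = names(ent))
}
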