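#' Options for the linear-combination fit
#'
#' @param fit_range ppm interval fitted (default 0.2-4.2 ppm).
#' @param baseline_knot_spacing Cubic B-spline baseline knot spacing in ppm
#'   (default 0.4); `NULL` disables the baseline.
#' @param phi0_bounds Zero-order phase bounds in degrees.
#' @param phi1 First-order phase in degrees per ppm, held fixed (basis and
#'   data built with the same acquisition delay need none).
#' @param max_global_shift Bound on the common frequency shift (ppm).
#' @param max_broadening Bound on the shared extra Gaussian broadening (Hz,
#'   FWHM).
#' @param per_component_shift Per-component shift bound in ppm for
#'   metabolite/MM entries (documented contract; individual metabolite
#'   shifts are held at zero by this fitter) and `lipid_shift` for
#'   shift-mobile lipid entries, which are optimized when
#'   `optimize_lipid_shifts` is `TRUE`.
#' @param lipid_shift Shift bound for lipid entries (ppm).
#' @param optimize_lipid_shifts Optimize individual lipid shifts.
#' @param optimize_phase,optimize_shift,optimize_broadening Toggle the
#'   global nonlinear parameters (freezing all three reduces the fit to a
#'   non-negative linear least-squares problem).
#' @param use_ratio_priors Apply soft concentration-ratio priors if the
#'   basis carries them (default `TRUE`).
#' @param ratio_prior_weight Dimensionless weight of the ratio-prior
#'   penalty (default 1).
#' @param naa_window,noise_window ppm windows used for the NAA line-width /
#'   SNR quality measures.
#' @param maxit Outer optimizer iteration cap.
#' @return A list of class `lc_fit_options`.
#' @export
lc_fit_options <- function(fit_range = c(0.2, 4.2),
                           baseline_knot_spacing = 0.4,
                           phi0_bounds = c(-45, 45),
                           phi1 = 0,
                           max_global_shift = 0.03,
                           max_broadening = 20,
                           per_component_shift = 0.01,
                           lipid_shift = 0.05,
                           optimize_lipid_shifts = FALSE,
                           optimize_phase = TRUE,
                           optimize_shift = TRUE,
                           optimize_broadening = TRUE,
                           use_ratio_priors = TRUE,
                           ratio_prior_weight = 1,
                           naa_window = c(1.90, 2.10),
                           noise_window = c(-3, -1),
                           maxit = 60) {
  structure(as.list(environment()), class = "lc_fit_options")
}

# Non-negative least squares (Lawson-Hanson active set on the normal
# equations). The design here is small (tens of columns) and is solved
# thousands of times per grid, so the active-set iteration works on the
# precomputed Gram matrix; near-collinear column pairs (Cr/PCr, GPC/PCh)
# are handled with a pseudo-inverse fallback. Returns the solution and the
# residual norm.
lc_nnls <- function(A, b) {
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  J <- ncol(A)
  x <- numeric(J)
  Pset <- logical(J)
  tol <- 1e-10 * max(diag(AtA))
  psolve <- function(M, v) tryCatch(solve(M, v), error = function(e)
    drop(pracma::pinv(M) %*% v))
  for (outer in seq_len(30L * J)) {
    w <- Atb - drop(AtA %*% x)
    cand <- which(!Pset)
    if (!length(cand) || max(w[cand]) <= tol) break
    Pset[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- numeric(J)
      z[Pset] <- psolve(AtA[Pset, Pset, drop = FALSE], Atb[Pset])
      if (all(z[Pset] > 0)) { x <- z; break }
      neg <- Pset & z <= 0
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (z - x)
      drop_set <- Pset & x <= tol
      Pset[drop_set] <- FALSE
      x[!Pset] <- 0
      if (!any(Pset)) break
    }
  }
  resid2 <- sum(b^2) - 2 * sum(x * Atb) + drop(crossprod(x, AtA %*% x))
  list(x = x, resid_norm = sqrt(max(resid2, 0)))
}

# Gaussian broadening envelope for extra FWHM gamma (Hz) in the time domain
broaden_envelope <- function(gamma_hz, t) {
  if (gamma_hz <= 0) return(rep(1, length(t)))
  exp(-(pi * gamma_hz)^2 / (4 * log(2)) * t^2)
}

#' Linear-combination model fit of a spectrum against a basis set
#'
#' Fits the real part of the spectrum over the analysis window as a
#' non-negative linear combination of basis spectra under a shared
#' zero-order phase, global frequency shift and global Gaussian
#' broadening, plus a cubic B-spline baseline. When the basis carries soft
#' concentration-ratio priors (a `con_*` MM model), deviations of fitted
#' MM amplitudes from `expected_ratio * a_MM1` are penalized with a
#' Gaussian prior of width `sd * a_MM1`, implemented as extra penalty rows
#' in the least-squares system and re-scaled over a few reweighting
#' passes. Amplitude CRLBs come from the Fisher information of the
#' amplitude block at the solution, with the noise level estimated from
#' the fit residual.
#'
#' @param spec An [mrs_spectrum()] or [fid_signal()].
#' @param basis A [basis_set()] on a compatible grid.
#' @param opts An [lc_fit_options()] list.
#' @return An object of class `lc_fit_result`: named `amplitudes` (>= 0)
#'   and `crlb_percent` (999 for unfittable entries), `combos` (tCr, tCho,
#'   Glx, tNAA sums with CRLBs where the members exist), `phi0`, `phi1`,
#'   `global_shift_ppm`, `broadening_hz`, `baseline`, `fitted`, `residual`
#'   and `ppm` on the fit grid, `fwhm_naa`, `snr_naa`, `noise_sd`,
#'   `objective`, `converged`.
#' @export
lc_fit <- function(spec, basis, opts = lc_fit_options()) {
  if (inherits(spec, "fid_signal")) spec <- fid_to_spectrum(spec)
  stopifnot(inherits(spec, "mrs_spectrum"), inherits(basis, "basis_set"))
  acq <- spec$acq
  if (acq$n_points != basis$acq$n_points ||
      abs(acq$dwell_time - basis$acq$dwell_time) > 1e-12)
    stop("basis acquisition grid incompatible with the spectrum")
  ppm <- spec$ppm_axis
  fit_idx <- which(ppm >= min(opts$fit_range) & ppm <= max(opts$fit_range))
  if (length(fit_idx) < 16) stop("fit range too narrow")
  ppm_fit <- ppm[fit_idx]
  step <- abs(ppm[1] - ppm[2])
  if (!is.null(opts$baseline_knot_spacing) &&
      opts$baseline_knot_spacing <= 2 * step)
    stop("baseline knot spacing must exceed twice the ppm grid step")
  t <- acq_time_axis(acq)
  nms <- names(basis$entries)
  J <- length(nms)

  S <- NULL
  if (!is.null(opts$baseline_knot_spacing)) {
    knots <- seq(min(ppm_fit), max(ppm_fit), by = opts$baseline_knot_spacing)
    knots <- knots[-c(1, length(knots))]
    S <- splines::bs(ppm_fit, knots = knots, degree = 3, intercept = TRUE)
    S <- matrix(as.numeric(S), nrow = length(ppm_fit))
  }

  rp <- if (isTRUE(opts$use_ratio_priors)) basis$ratio_priors else NULL
  if (!is.null(rp)) {
    if (!"MM1" %in% nms) stop("ratio priors present but MM1 not in basis")
    rp <- rp[rp$numerator %in% nms, , drop = FALSE]
  }

  lip_idx <- match(basis$lipid_names, nms)
  n_lip <- if (isTRUE(opts$optimize_lipid_shifts)) length(lip_idx) else 0L

  y <- Re(spec$values[fit_idx])

  # theta = (phi0_deg?, shift_ppm?, gamma_hz?, lipid shifts...)
  use <- c(phase = opts$optimize_phase, shift = opts$optimize_shift,
           broad = opts$optimize_broadening)
  th0 <- c(if (use["phase"]) 0, if (use["shift"]) 0, if (use["broad"]) 0.05,
           rep(0, n_lip))
  lower <- c(if (use["phase"]) opts$phi0_bounds[1],
             if (use["shift"]) -opts$max_global_shift,
             if (use["broad"]) 0, rep(-opts$lipid_shift, n_lip))
  upper <- c(if (use["phase"]) opts$phi0_bounds[2],
             if (use["shift"]) opts$max_global_shift,
             if (use["broad"]) opts$max_broadening,
             rep(opts$lipid_shift, n_lip))

  unpack <- function(th) {
    i <- 0L
    phi0 <- if (use["phase"]) th[(i <- i + 1L)] else 0
    shift <- if (use["shift"]) th[(i <- i + 1L)] else 0
    gamma <- if (use["broad"]) th[(i <- i + 1L)] else 0
    lsh <- if (n_lip) th[i + seq_len(n_lip)] else numeric(0)
    list(phi0 = phi0, shift = shift, gamma = gamma, lipid_shift = lsh)
  }

  # display-order index permutation of the raw DFT, restricted to the fit
  # window: values[fit_idx] == fft(x)[perm_fit]
  n <- acq$n_points
  perm <- rev(c((n %/% 2 + 1):n, 1:(n %/% 2)))
  perm_fit <- perm[fit_idx]

  design <- function(th) {
    p <- unpack(th)
    genv <- broaden_envelope(p$gamma, t)
    shift_hz <- p$shift * acq$transmitter_frequency
    phase <- exp(-1i * (p$phi0 + opts$phi1 * (ppm_fit - acq$reference_ppm)) *
                 pi / 180)
    shift_env <- if (shift_hz != 0) exp(2i * pi * shift_hz * t) else NULL
    C <- matrix(0, length(fit_idx), J)
    for (j in seq_len(J)) {
      x <- basis$entries[[j]] * genv
      if (!is.null(shift_env)) x <- x * shift_env
      if (n_lip && j %in% lip_idx) {
        lsh <- p$lipid_shift[match(j, lip_idx)] * acq$transmitter_frequency
        if (lsh != 0) x <- x * exp(2i * pi * lsh * t)
      }
      C[, j] <- Re(phase * stats::fft(x)[perm_fit])
    }
    C
  }

  # spline block is unconstrained: project it out once (QR) so the NNLS
  # only sees the amplitude columns; the eliminated baseline is recovered
  # after the fit
  qr_S <- if (!is.null(S)) qr(S) else NULL
  y_perp <- if (is.null(qr_S)) y else qr.resid(qr_S, y)
  a1_cache <- new.env(parent = emptyenv())
  a1_cache$val <- NULL

  # Spectral noise level, estimated from the signal-free window: puts the
  # ratio-prior penalty on the same footing as the (unstandardized)
  # residual, i.e. a unit-weight prior behaves as a Gaussian prior with
  # width sd * a_MM1 under the estimated noise.
  sigma0 <- {
    nidx <- which(ppm >= min(opts$noise_window) & ppm <= max(opts$noise_window))
    if (length(nidx) >= 8) stats::sd(Re(spec$values[nidx]))
    else stats::sd(utils::tail(y, max(16, length(y) %/% 20)))
  }

  prior_rows <- function(a1_hat) {
    P <- matrix(0, nrow(rp), J)
    for (q in seq_len(nrow(rp))) {
      s <- sqrt(opts$ratio_prior_weight) * sigma0 / (rp$sd[q] * a1_hat)
      P[q, match(rp$numerator[q], nms)] <- s
      P[q, match("MM1", nms)] <- -s * rp$expected_ratio[q]
    }
    P
  }

  # The prior rows are scaled by the MM1 amplitude. During the outer
  # optimization that scale is frozen at its value from an unpenalized
  # solve at the starting point, so the objective is a deterministic
  # function of theta; the final solve re-iterates the scale to
  # self-consistency.
  solve_amps <- function(C, final = FALSE) {
    Cp <- if (is.null(qr_S)) C else qr.resid(qr_S, C)
    if (is.null(rp) || nrow(rp) == 0) {
      sol <- lc_nnls(Cp, y_perp)
      return(list(a = sol$x, obj = sol$resid_norm, P = NULL))
    }
    if (is.null(a1_cache$val)) {
      sol0 <- lc_nnls(Cp, y_perp)
      a1_cache$val <- max(sol0$x[match("MM1", nms)], 1e-12)
    }
    a1_hat <- a1_cache$val
    n_pass <- if (final) 4L else 1L
    for (it in seq_len(n_pass)) {
      P <- prior_rows(a1_hat)
      sol <- lc_nnls(rbind(Cp, P), c(y_perp, rep(0, nrow(rp))))
      a1_new <- max(sol$x[match("MM1", nms)], 1e-12)
      done <- abs(a1_new - a1_hat) < 1e-6 * a1_hat
      if (it < n_pass) a1_hat <- a1_new
      if (done) break
    }
    list(a = sol$x, obj = sol$resid_norm, P = P)
  }

  objfun <- function(th) solve_amps(design(th))$obj

  converged <- TRUE
  if (length(th0)) {
    pscale <- c(if (use["phase"]) 5, if (use["shift"]) 0.005,
                if (use["broad"]) 1, rep(0.01, n_lip))
    op <- stats::optim(th0, objfun, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = opts$maxit, factr = 1e7,
                                      parscale = pscale,
                                      ndeps = 0.01 * pscale))
    th <- op$par
    converged <- op$convergence == 0
    # the no-extra-broadening boundary is a common optimum: test it
    if (use["broad"]) {
      i_b <- sum(use[c("phase", "shift")]) + 1L
      if (th[i_b] > 0) {
        th_b <- th; th_b[i_b] <- 0
        if (objfun(th_b) < op$value) { th <- th_b; converged <- TRUE }
      }
    }
  } else th <- numeric(0)

  C <- design(th)
  sol <- solve_amps(C, final = TRUE)
  amps <- sol$a[seq_len(J)]
  names(amps) <- nms
  baseline <- if (!is.null(qr_S)) {
    coef <- qr.coef(qr_S, y - C %*% amps)
    coef[is.na(coef)] <- 0
    as.vector(S %*% coef)
  } else rep(0, length(fit_idx))
  fitted_sig <- as.vector(C %*% amps)
  residual <- y - fitted_sig - baseline
  noise_sd <- stats::sd(residual)

  crlb <- lc_crlb(C, sol$P, amps, noise_sd)

  combos <- lc_combos(amps, crlb$cov, list(
    tCr = c("Cr", "PCr"), tCho = c("GPC", "PCh"),
    Glx = c("Glu", "Gln"), tNAA = c("NAA", "NAAG")))

  p <- unpack(th)
  sp_ph <- phase_correct(spec, p$phi0, opts$phi1)
  pm <- tryCatch(measure_peak(sp_ph, opts$naa_window, opts$noise_window),
                 error = function(e) list(fwhm_hz = NA_real_, snr = NA_real_))
  # lipid-contamination screen: signal mass in the lipid/MM window relative
  # to the NAA window; extracerebral contamination drives this ratio up by
  # an order of magnitude
  lipid_area_ratio <- {
    lw <- ppm >= 0.8 & ppm <= 1.5
    nw <- ppm >= 1.85 & ppm <= 2.15
    den <- sum(Re(sp_ph$values[nw]))
    if (abs(den) > 0) sum(Re(sp_ph$values[lw])) / den else Inf
  }

  structure(list(amplitudes = amps, crlb_percent = crlb$pct,
                 combos = combos,
                 phi0 = p$phi0, phi1 = opts$phi1,
                 global_shift_ppm = p$shift, broadening_hz = p$gamma,
                 lipid_shift_ppm = p$lipid_shift,
                 ppm = ppm_fit, baseline = baseline, fitted = fitted_sig,
                 residual = residual, noise_sd = noise_sd,
                 fwhm_naa = pm$fwhm_hz, snr_naa = pm$snr,
                 lipid_area_ratio = lipid_area_ratio,
                 objective = sol$obj, converged = converged),
            class = "lc_fit_result")
}

# Fisher-information CRLBs for the amplitude block. Penalty rows (soft
# priors) contribute their own information. Entries fitted at zero report
# the 999 sentinel.
lc_crlb <- function(C_data, C_pen, amps, noise_sd) {
  FI <- crossprod(C_data) / max(noise_sd^2, .Machine$double.eps)
  if (!is.null(C_pen)) FI <- FI + crossprod(C_pen)
  cov <- tryCatch(solve(FI), error = function(e) {
    warning("singular Fisher information in LC fit; per-entry CRLB set to Inf")
    matrix(Inf, length(amps), length(amps))
  })
  sds <- sqrt(pmax(diag(cov), 0))
  pct <- ifelse(amps > 0, 100 * sds / amps, 999)
  pct[!is.finite(pct) | pct > 999] <- 999
  names(pct) <- names(amps)
  list(pct = pct, cov = cov)
}

lc_combos <- function(amps, cov, defs) {
  out <- list()
  for (nm in names(defs)) {
    members <- defs[[nm]]
    if (!all(members %in% names(amps))) next
    v <- as.numeric(names(amps) %in% members)
    a <- sum(amps[members])
    var_c <- if (all(is.finite(cov))) as.numeric(t(v) %*% cov %*% v) else Inf
    out[[nm]] <- c(amplitude = a,
                   crlb_percent = if (a > 0 && is.finite(var_c))
                     min(100 * sqrt(max(var_c, 0)) / a, 999) else 999)
  }
  out
}

#' @export
print.lc_fit_result <- function(x, ...) {
  cat(sprintf("<lc_fit_result> %d entries, phi0 %.1f deg, shift %.4f ppm, broadening %.2f Hz\n",
              length(x$amplitudes), x$phi0, x$global_shift_ppm, x$broadening_hz))
  tab <- data.frame(amplitude = x$amplitudes, crlb_pct = x$crlb_percent)
  print(utils::head(tab[order(-tab$amplitude), ], 12), digits = 3)
  invisible(x)
}
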