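#' MRSI grid container
#'
#' A square grid of FIDs with a brain mask and per-voxel tissue fractions.
#' Voxel indices are row/column of the array, k-space operations assume the
#' DC term at index `n/2 + 1` after centering.
#'
#' @param fids Complex array `n x n x n_points`.
#' @param mask Logical `n x n` matrix.
#' @param acq An [acq_params()] object.
#' @param f_gm,f_wm,f_csf Tissue fraction matrices in `[0, 1]`, per-voxel
#'   sums at most 1 (+ small numerical slack).
#' @return An object of class `mrsi_grid`.
#' @export
mrsi_grid <- function(fids, mask, acq, f_gm = NULL, f_wm = NULL, f_csf = NULL) {
  stopifnot(inherits(acq, "acq_params"), length(dim(fids)) == 3,
            dim(fids)[1] == dim(fids)[2], dim(fids)[3] == acq$n_points,
            is.logical(mask), all(dim(mask) == dim(fids)[1:2]))
  n <- dim(fids)[1]
  zero <- matrix(0, n, n)
  f_gm <- f_gm %||% zero; f_wm <- f_wm %||% zero; f_csf <- f_csf %||% zero
  tot <- f_gm + f_wm + f_csf
  if (any(f_gm < 0 | f_wm < 0 | f_csf < 0) || any(tot > 1.0001))
    stop("tissue fractions must lie in [0,1] and sum to at most 1 per voxel")
  mask3 <- array(mask, dim = dim(fids))
  if (any(!is.finite(Re(fids[mask3]))) || any(!is.finite(Im(fids[mask3]))))
    stop("masked voxels must contain finite FIDs")
  structure(list(fids = fids, mask = mask, acq = acq,
                 f_gm = f_gm, f_wm = f_wm, f_csf = f_csf, n = n),
            class = "mrsi_grid")
}

#' @export
print.mrsi_grid <- function(x, ...) {
  cat(sprintf("<mrsi_grid> %d x %d, %d masked voxels, %d pts/FID\n",
              x$n, x$n, sum(x$mask), dim(x$fids)[3]))
  invisible(x)
}

#' Extract one voxel as an FID
#' @param grid An `mrsi_grid`.
#' @param i,j Voxel indices.
#' @return An [fid_signal()].
#' @export
grid_voxel <- function(grid, i, j) fid_signal(grid$fids[i, j, ], grid$acq)

#' Quantify every masked voxel of an MRSI grid
#'
#' Runs [lc_fit()] independently per masked voxel (results do not depend on
#' evaluation order); per-voxel failures are recorded and never abort the
#' grid.
#'
#' @param grid An [mrsi_grid()].
#' @param basis A [basis_set()].
#' @param opts [lc_fit_options()].
#' @param progress Print a progress line every 64 voxels.
#' @return An object of class `mrsi_fit`: matrices `amplitudes` and
#'   `crlb_percent` (voxels x entries, incl. combo columns), per-voxel
#'   `fwhm_naa`, `snr_naa`, `crlb_naa`, `converged`, `failed`, the voxel
#'   index table `voxels`, and the originating `grid`.
#' @export
quantify_grid <- function(grid, basis, opts = lc_fit_options(),
                          progress = FALSE) {
  stopifnot(inherits(grid, "mrsi_grid"))
  vox <- which(grid$mask, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("empty mask")
  nms <- names(basis$entries)
  nv <- nrow(vox)
  amps <- matrix(NA_real_, nv, length(nms), dimnames = list(NULL, nms))
  crlb <- matrix(NA_real_, nv, length(nms), dimnames = list(NULL, nms))
  combo_names <- c("tCr", "tCho", "Glx", "tNAA")
  camps <- matrix(NA_real_, nv, 4, dimnames = list(NULL, combo_names))
  ccrlb <- matrix(NA_real_, nv, 4, dimnames = list(NULL, combo_names))
  fwhm_naa <- snr_naa <- lipid_ratio <- rep(NA_real_, nv)
  converged <- failed <- rep(FALSE, nv)
  for (k in seq_len(nv)) {
    res <- tryCatch(lc_fit(grid_voxel(grid, vox[k, 1], vox[k, 2]), basis, opts),
                    error = function(e) e)
    if (inherits(res, "error")) { failed[k] <- TRUE; next }
    amps[k, ] <- res$amplitudes
    crlb[k, ] <- res$crlb_percent
    for (cn in names(res$combos)) {
      camps[k, cn] <- res$combos[[cn]]["amplitude"]
      ccrlb[k, cn] <- res$combos[[cn]]["crlb_percent"]
    }
    fwhm_naa[k] <- res$fwhm_naa
    snr_naa[k] <- res$snr_naa
    lipid_ratio[k] <- res$lipid_area_ratio
    converged[k] <- res$converged
    if (progress && k %% 64 == 0)
      message(sprintf("  %d / %d voxels", k, nv))
  }
  structure(list(amplitudes = cbind(amps, camps),
                 crlb_percent = cbind(crlb, ccrlb),
                 entry_names = nms, combo_names = combo_names,
                 crlb_naa = if ("NAA" %in% nms) crlb[, "NAA"] else rep(NA_real_, nv),
                 fwhm_naa = fwhm_naa, snr_naa = snr_naa,
                 lipid_area_ratio = lipid_ratio,
                 converged = converged, failed = failed,
                 voxels = vox, grid = grid),
            class = "mrsi_fit")
}

#' @export
print.mrsi_fit <- function(x, ...) {
  cat(sprintf("<mrsi_fit> %d voxels (%d failed), %d basis entries\n",
              nrow(x$voxels), sum(x$failed), length(x$entry_names)))
  invisible(x)
}

#' Quality-assurance filter on NAA reliability and line width
#'
#' A voxel is automatically excluded only when both criteria fail:
#' `CRLB_NAA > crlb_limit` AND `FWHM_NAA > fwhm_limit` (strict
#' inequalities; a voxel exactly at both limits is retained). Voxels
#' failing exactly one criterion are flagged for visual inspection but
#' never excluded automatically, keeping the pipeline deterministic.
#' Fit failures are excluded.
#'
#' Optionally, voxels whose lipid-window signal mass exceeds
#' `lipid_area_limit` times the NAA-window mass are excluded as
#' lipid-contaminated (the rim-voxel screen; off by default). A third of
#' the NAA mass is far above anything the macromolecules and lactate
#' produce in uncontaminated brain.
#'
#' @param fit An `mrsi_fit`.
#' @param fwhm_limit NAA line-width limit in Hz (default 20).
#' @param crlb_limit NAA CRLB limit in percent (default 30).
#' @param lipid_area_limit Lipid-to-NAA area ratio limit (default `NULL`
#'   = screen off; 1/3 is the recommended value).
#' @return An object of class `qa_result`: logical `excluded`, `reason`
#'   (`"none"`, `"auto"`, `"flagged_single_criterion"`, `"lipid"`,
#'   `"failed"`), and the per-voxel `stats`.
#' @export
qa_filter <- function(fit, fwhm_limit = 20, crlb_limit = 30,
                      lipid_area_limit = NULL) {
  stopifnot(inherits(fit, "mrsi_fit"))
  crlb <- fit$crlb_naa
  fwhm <- fit$fwhm_naa
  bad_crlb <- !is.na(crlb) & crlb > crlb_limit
  bad_fwhm <- !is.na(fwhm) & fwhm > fwhm_limit
  excluded <- (bad_crlb & bad_fwhm) | fit$failed
  reason <- rep("none", length(crlb))
  reason[xor(bad_crlb, bad_fwhm)] <- "flagged_single_criterion"
  reason[bad_crlb & bad_fwhm] <- "auto"
  if (!is.null(lipid_area_limit)) {
    lip <- !is.na(fit$lipid_area_ratio) &
      fit$lipid_area_ratio > lipid_area_limit
    excluded <- excluded | lip
    reason[lip] <- "lipid"
  }
  reason[fit$failed] <- "failed"
  structure(list(excluded = excluded, reason = reason,
                 stats = data.frame(crlb_naa = crlb, fwhm_naa = fwhm,
                                    lipid_area_ratio = fit$lipid_area_ratio),
                 fwhm_limit = fwhm_limit, crlb_limit = crlb_limit,
                 lipid_area_limit = lipid_area_limit),
            class = "qa_result")
}

#' Per-component amplitude map with reliability masking
#'
#' @param fit An `mrsi_fit`.
#' @param qa A [qa_filter()] result.
#' @param component Basis entry or combo name.
#' @param crlb_threshold Per-component CRLB display threshold in percent
#'   (default 30); voxels above it are undefined (`NA`).
#' @return A matrix of class `component_map` (`NA` = undefined).
#' @export
make_map <- function(fit, qa, component, crlb_threshold = 30) {
  stopifnot(inherits(fit, "mrsi_fit"))
  if (!component %in% colnames(fit$amplitudes))
    stop("unknown component: ", component)
  n <- fit$grid$n
  m <- matrix(NA_real_, n, n)
  a <- fit$amplitudes[, component]
  cr <- fit$crlb_percent[, component]
  ok <- !qa$excluded & !is.na(a) & !is.na(cr) & cr <= crlb_threshold
  m[fit$voxels[ok, , drop = FALSE]] <- a[ok]
  structure(m, class = c("component_map", "matrix", "array"),
            component = component)
}

#' Downsample tissue probability maps through k-space truncation
#'
#' Matches high-resolution segmentation maps to the MRSI resolution and
#' point-spread function: each map is Fourier-transformed, the central
#' `target x target` k-space block retained (optionally restricted to an
#' inscribed ellipse, mirroring elliptical k-space sampling), transformed
#' back, and the real part clipped to `[0, 1]`. The image mean (DC term)
#' is preserved exactly before clipping. If clipped fractions of a voxel
#' sum above 1, they are renormalized to sum 1.
#'
#' @param seg Named list of 2 or 3 equal-size probability matrices (values
#'   in `[0, 1.001]`), e.g. `list(gm = ..., wm = ..., csf = ...)`.
#' @param target_matrix Target (MRSI) matrix size; must divide into the
#'   high-resolution size evenly in the sense `nrow(seg) >= target`.
#' @param elliptical_k Apply the inscribed elliptical k-space mask.
#' @return Named list of `target x target` fraction matrices.
#' @export
downsample_tissue_maps <- function(seg, target_matrix, elliptical_k = FALSE) {
  stopifnot(is.list(seg), length(seg) >= 1)
  nh <- nrow(seg[[1]])
  for (m in seg) {
    stopifnot(is.matrix(m), nrow(m) == nh, ncol(m) == nh)
    if (any(m < 0) || any(m > 1.001)) stop("non-probability input (outside [0, 1.001])")
  }
  if (target_matrix > nh) stop("target matrix exceeds segmentation resolution")
  tm <- target_matrix
  fftshift2 <- function(A) {
    n1 <- nrow(A); n2 <- ncol(A)
    A[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)), c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))]
  }
  ell <- NULL
  if (elliptical_k) {
    cc <- (seq_len(tm) - 1 - tm %/% 2) / (tm / 2)
    ell <- outer(cc, cc, function(a, b) a^2 + b^2 <= 1 + 1e-12)
  }
  out <- lapply(seg, function(m) {
    Fm <- fftshift2(stats::fft(m))
    ctr <- nh %/% 2 + 1
    idx <- (ctr - tm %/% 2):(ctr + tm %/% 2 - 1)
    crop <- Fm[idx, idx]
    if (!is.null(ell)) crop[!ell] <- 0
    crop <- fftshift2(crop)  # back to standard DFT order (even sizes)
    img <- Re(stats::fft(crop, inverse = TRUE)) / (nh * nh)
    img
  })
  pre_clip <- out
  out <- lapply(out, function(m) pmin(pmax(m, 0), 1))
  tot <- Reduce(`+`, out)
  over <- tot > 1
  if (any(over)) {
    out <- lapply(out, function(m) { m[over] <- m[over] / tot[over]; m })
  }
  attr(out, "pre_clip") <- pre_clip
  out
}

#' Regression of a component map on the gray-matter fraction
#'
#' Ordinary least squares of amplitude on the CSF-free gray-matter
#' fraction `f_GM / (f_GM + f_WM)` (or raw `f_GM`), over voxels that are
#' defined in the map and have CSF fraction at or below `csf_limit`.
#' CRLB-based masking is already encoded in the map (undefined voxels).
#'
#' @param map A [make_map()] result.
#' @param grid The corresponding [mrsi_grid()] (tissue fractions).
#' @param csf_limit Maximum CSF fraction (default 0.2).
#' @param gm_definition `"csf_free"` (default) or `"raw"`.
#' @param min_voxels Minimum eligible voxels (default 10).
#' @return List with `slope`, `intercept`, `r`, `n`, and the fitted `lm`.
#' @export
gm_fraction_regression <- function(map, grid, csf_limit = 0.2,
                                   gm_definition = c("csf_free", "raw"),
                                   min_voxels = 10) {
  gm_definition <- match.arg(gm_definition)
  stopifnot(inherits(grid, "mrsi_grid"))
  gmf <- if (gm_definition == "raw") grid$f_gm else {
    tot <- grid$f_gm + grid$f_wm
    g <- matrix(NA_real_, grid$n, grid$n)
    g[tot > 0] <- grid$f_gm[tot > 0] / tot[tot > 0]
    g
  }
  eligible <- !is.na(map) & !is.na(gmf) & grid$f_csf <= csf_limit
  n_el <- sum(eligible)
  if (n_el < min_voxels)
    stop("insufficient data: ", n_el, " eligible voxels (need >= ", min_voxels, ")")
  x <- gmf[eligible]; yv <- map[eligible]
  if (stats::sd(x) < 1e-12)
    stop("degenerate gray-matter fraction: no variation across eligible voxels")
  fit <- stats::lm(yv ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, yv), n = n_el, model = fit)
}

#' Write tissue fraction maps or component maps as NIfTI
#'
#' @param maps Named list of matrices.
#' @param path Output file (`.nii` / `.nii.gz`), one volume per map.
#' @return `path`, invisibly.
#' @export
write_maps_nifti <- function(maps, path) {
  arr <- simplify2array(maps)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read tissue probability maps from NIfTI
#'
#' @param path NIfTI file with 2 or 3 volumes (GM, WM, CSF order).
#' @return Named list of matrices.
#' @export
read_tissue_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  arr <- as.array(arr)
  if (length(dim(arr)) == 2) return(list(gm = arr))
  out <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  names(out) <- c("gm", "wm", "csf")[seq_along(out)]
  out
}

#' Long-format table of an MRSI fit
#'
#' @param fit An `mrsi_fit`.
#' @param qa Optional [qa_filter()] result to annotate exclusions.
#' @return Data frame with one row per voxel x component.
#' @export
mrsi_fit_table <- function(fit, qa = NULL) {
  stopifnot(inherits(fit, "mrsi_fit"))
  nv <- nrow(fit$voxels)
  comps <- colnames(fit$amplitudes)
  out <- data.frame(
    row = rep(fit$voxels[, 1], times = length(comps)),
    col = rep(fit$voxels[, 2], times = length(comps)),
    component = rep(comps, each = nv),
    amplitude = as.vector(fit$amplitudes),
    crlb_percent = as.vector(fit$crlb_percent),
    stringsAsFactors = FALSE)
  if (!is.null(qa)) out$excluded <- rep(qa$excluded, times = length(comps))
  out
}
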