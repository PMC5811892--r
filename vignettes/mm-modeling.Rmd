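---
title: "Modeling individual macromolecule components in 7T FID-MRSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling individual macromolecule components in 7T FID-MRSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsimm)
```

## The problem

Proton MR spectra of the brain acquired with ultra-short acquisition delay
(TE* ~ 1.3 ms) at 7 T contain, underneath the metabolite resonances, a set
of broad signals from cytosolic proteins — the macromolecules (MM). Nine
distinct MM peaks between 0.90 and 3.77 ppm can be resolved at this field
strength (a tenth near 4.3 ppm sits too close to water to be modeled).
Quantification that ignores them is badly biased; the conventional remedy
— including a single measured metabolite-nulled spectrum in the fitting
basis — removes the bias but discards all information about the individual
peaks and fails when individual MM components are pathologically altered.

`mrsimm` implements the alternative: parameterize the metabolite-nulled MM
spectrum into nine individual components, rebuild the quantification basis
around them, and fit metabolites and MM components *simultaneously* in
every voxel of a 2D FID-MRSI grid.

## Signal model and conventions

All signals are complex FIDs `x(t)` sampled at 6,000 Hz (2,048 points in
the standard protocols). A spectral component with amplitude $A$, phase
$\phi$, center frequency $f$ and full width at half maximum $w$ (Hz)
contributes

$$A e^{i\phi} e^{2\pi i f t} g(t), \qquad
g(t) = \begin{cases} e^{-\beta t^2}, & \beta = (\pi w)^2 / (4\ln 2)
  & \text{(Gaussian)}\\
  e^{-\pi w t} & \text{(Lorentzian)}\end{cases}$$

Chemical shift is `reference_ppm + f / transmitter_frequency` with the
water reference fixed at 4.7 ppm by default and a 7 T proton transmitter
frequency of 297.22 MHz; both are configurable, since referencing
conventions differ between sites. Spectra are stored in display order
(ppm strictly decreasing) with an explicit axis. The DFT pair is plain
and unitary up to the usual $1/n$; halving of the first FID point is
available (`halve_first_point`) but off by default so that Parseval's
identity and the round trip hold exactly.

## Parameterizing the metabolite-nulled spectrum

Metabolite-nulled spectra retain small residuals of NAA (2.01 ppm),
myo-inositol (3.52), Glu (2.30), Gln (2.45) and total creatine (3.98 ppm).
`remove_metabolite_residuals()` fits these five narrow lines *jointly*
with a broad nine-peak MM stand-in — so the baseline under the residuals
is represented rather than absorbed — and subtracts only the narrow
components.

Two parameterizations of the cleaned, averaged spectrum are provided.

**Prior-knowledge nonlinear least squares** (`parameterize_mm_amares()`,
AMARES-style): nine Gaussian components with bounded centers
(±0.08 ppm around the standard positions), bounded widths (8–60 Hz) and
free phases, fitted in the time domain by bounded Levenberg–Marquardt
with an analytic Jacobian. Amplitudes and phases are initialized by a
linear (variable-projection) solve at the prior nonlinear parameters.
CRLBs per parameter come from the Fisher information at the solution,
with the noise variance estimated from the last 10% of the FID — the
tail is signal-free for these rapidly decaying signals.

**Hankel-SVD decomposition** (`parameterize_mm_hlsvd()`, HLSVD-style):
the FID is arranged into a Hankel matrix, rank-truncated to 13 components
(the minimum that yields flat residuals for this class of spectra),
poles estimated from the shift-invariance of the left singular vectors,
amplitudes by linear least squares. The Lanczos iteration of the
classical implementation is an efficiency device only; at 2,048 points a
full SVD is equivalent, and 512 Hankel rows (rather than $n/2$ = 1,024)
give identical poles for these broad, rapidly decaying signals at a
third of the cost. Components that do not represent MM signal are then
removed: anything outside 0.5–4.0 ppm or broader than 50 Hz (all
plausible MM peaks at 7 T are far narrower; broader terms model the
baseline). Because a single broad peak is routinely represented by two
nearby Lorentzian poles, the survivors are clustered by chemical-shift
proximity (gap 0.1 ppm — about half the smallest separation between the
standard MM positions) into nine peaks; each cluster's basis FID is the
exact complex sum of its members.

A known limitation, deliberately left visible: a weak, broad peak
flanked by a strong neighbor (the 1.67 ppm component in the default
synthetic truth, 0.12 ppm wide next to the strong 2.04 ppm peak) picks
up a systematic center bias of ~0.05 ppm in the Hankel-SVD route — the
pole budget preferentially doubles up on strong peaks, and the
Lorentzian model class cannot represent the Gaussian shoulder it leaves
behind. The prior-knowledge fit recovers the same component to better
than 0.02 ppm. This reproduces, on synthetic data, the qualitative
finding that the SVD route yields the weaker MM model, with broader
lineshapes on Gaussian truth (compare the mean fitted widths of the two
routes).

## The seven MM models and the basis sets

```{r variants, eval = FALSE}
truth  <- default_mm_truth()            # synthetic 9-peak ground truth
nulled <- lapply(1:6, function(s)
  generate_mm_fid(truth, noise_sd = 0.02, seed = s))
avg    <- fid_signal(Reduce(`+`, lapply(nulled, `[[`, "samples")) / 6,
                     acq_nulled_7t())

ind_am <- parameterize_mm_amares(avg)           # 2b: 9 components
grp_am <- group_mm_components(ind_am)           # 3b: 4 groups
con_am <- mm_model_with_priors(ind_am,          # 4b: 9 components + priors
                               derive_ratio_priors(nulled))
full   <- full_mm_model(nulled)                 # 1: single component
```

Seven variants are supported: the full measured spectrum (`full_MM`),
individual components from either parameterization (`ind_MM_AM`,
`ind_MM_HL`), four fixed groups MM1–MM4 / MM5–MM6 / MM7–MM8 / MM9
(`grp_MM_AM`, `grp_MM_HL`; amplitudes and phases frozen at the
parameterization values within each group), and individual components
under soft concentration-ratio priors (`con_MM_AM`, `con_MM_HL`).

Ratio priors use MM1 (0.9 ppm) as the denominator — it is strong, easy
to quantify, and overlaps no metabolite. `derive_ratio_priors()` fits
each of several nulled spectra, forms MM(X)/MM1 amplitude ratios, and
returns their means and SDs, with the SD floored at 10% of the mean so
that noiseless inputs cannot create degenerate hard constraints. The
priors are data carried by the basis; the package does not auto-tune
them.

`build_basis()` combines an MM model with 17 simulated metabolite
signals (glucose, Asp, GPC, PCh, Cr, PCr, GABA, Glu, Gln, GSH, glycine,
lactate, myo-inositol, NAA, NAAG, scyllo-inositol, taurine). Metabolites
are simulated from weak-coupling line lists (chemical shift + relative
amplitude per proton group, shared T2*): at TE* = 1.3 ms there is no
J-evolution to model, so density-matrix simulation would add nothing.
The first 39 points of each metabolite FID are dropped at a 5x
oversampled bandwidth (39 / 30 kHz = 1.3 ms = TE*), implemented exactly
as an analytic time shift, which reproduces the first-order phase ramp
of the acquisition. The basis writes to (and round-trips from) a
documented plain-text format with the ratio priors embedded as header
records.

## Linear-combination fitting

`lc_fit()` fits the real part of the spectrum over 4.2–0.2 ppm as a
non-negative linear combination of basis spectra under a shared
zero-order phase, a global frequency shift, and a shared extra Gaussian
broadening, plus a cubic B-spline baseline with knots every 0.4 ppm.
Design choices that were genuinely open:

* **Real-part fitting** after phase optimization, LCModel-style;
  switchable inputs are accepted as FID or spectrum.
* **Inner/outer split**: amplitudes (non-negative) and spline
  coefficients (free) are solved exactly for each candidate set of
  nonlinear parameters — the spline block is projected out by QR once,
  and the amplitudes solved by a Lawson–Hanson active-set iteration on
  the normal equations — while the three global nonlinear parameters are
  optimized by bounded quasi-Newton iteration. With basis and data built
  at the same acquisition delay there is no residual first-order phase,
  so `phi1` is exposed but fixed at 0 by default.
* **Per-component shifts** are held at zero for metabolite and MM
  entries (the global shift absorbs the per-voxel frequency offset;
  freeing ~26 coupled shift parameters per voxel buys nothing on
  realizable data and costs identifiability). Lipid entries, whose in
  vivo position genuinely varies, may optimize individual shifts within
  ±0.05 ppm when enabled.
* **Ratio-prior penalty**: for each prior, a row
  $\sqrt{w}\,\hat\sigma\,(a_x - r_x a_{\mathrm{MM1}}) / (\sigma_x\,
  \hat a_{\mathrm{MM1}})$ is appended to the least-squares system —
  a Gaussian prior of width $\sigma_x a_{\mathrm{MM1}}$ on the amplitude
  ratio. The spectral noise level $\hat\sigma$ (estimated from the
  signal-free window) makes unit weight mean exactly "one prior SD costs
  one noise SD"; without that factor the penalty would be numerically
  inert against an unstandardized residual. The MM1 scale
  $\hat a_{\mathrm{MM1}}$ is frozen during the outer optimization (so
  the objective is a deterministic function of the nonlinear parameters)
  and re-iterated to self-consistency in the final solve.
* **CRLBs** per amplitude from the Fisher information of the amplitude
  block at the solution, noise level estimated from the fit residual;
  prior rows contribute their own information. Entries fitted at zero
  report the 999% sentinel. Sums (tCr = Cr + PCr, tCho = GPC + PCh, Glx,
  tNAA) are reported with covariance-correct CRLBs.

## Grid pipeline, QA and tissue analysis

`quantify_grid()` applies `lc_fit()` independently to every masked voxel
(results are order-independent by construction). `qa_filter()`
implements the conjunctive rule — a voxel is automatically excluded only
if CRLB(NAA) > 30% **and** FWHM(NAA) > 20 Hz, strict inequalities —
while voxels failing a single criterion are flagged for inspection,
never silently dropped. An optional lipid screen excludes voxels whose
real-spectrum signal mass at 0.8–1.5 ppm exceeds one third of the
NAA-window mass: uncontaminated brain stays an order of magnitude below
that, extracerebral lipid an order of magnitude above, so the threshold
sits in a wide empty gap. This mirrors the quality-assurance step that
rules out lipid-contaminated rim voxels before analysis; the main basis
deliberately carries no lipid components (adding them lets clean voxels
absorb noise into the broad lipid shapes and biases MM1 by ~10%).

`make_map()` renders per-component maps with voxels masked where
excluded or where that component's CRLB exceeds 30%.
`downsample_tissue_maps()` matches high-resolution GM/WM/CSF probability
maps to the MRSI point-spread function by Fourier transform, central
k-space truncation (optionally with the inscribed elliptical mask,
mirroring elliptical k-space sampling), inverse transform, and clipping
to [0, 1]; the image mean (DC term) is preserved exactly before
clipping. `gm_fraction_regression()` regresses a component map on the
CSF-free gray-matter fraction `f_GM / (f_GM + f_WM)` — "GM fraction" has
no universal formula, so the CSF-free definition is the package default
and raw `f_GM` is available — excluding voxels with CSF fraction above
20%.

`compare_methods()` reproduces the statistical comparison: per-subject
averaging, per-metabolite one-way repeated-measures ANOVA across methods
(no sphericity correction by default; a Greenhouse–Geisser option
exists), paired post-hoc tests against `full_MM` with a Bonferroni
factor equal to the number of non-reference methods, and percent
differences with positive = above the reference. No correction is
applied across metabolites.

## The synthetic-data generator

All tests and acceptance analyses run on synthetic data, generated under
fixed study conditions:

* **Metabolite-nulled spectra**: nine Gaussian peaks at 0.90, 1.21,
  1.43, 1.67, 2.04, 2.26, 2.99, 3.21, 3.77 ppm. Only the positions are
  established values; amplitudes (1.00, 0.45, 0.40, 0.30, 0.70, 0.50,
  0.45, 0.40, 0.75) and widths (0.045–0.12 ppm) are fixture choices
  following the visual prominence order MM1 ≥ MM9 ≥ MM5 > others —
  in vivo MM amplitude ratios are not available and the fixtures are
  never asserted against literature values. Metabolite residuals are
  3 Hz Lorentzians at the five printed positions, scaled relative to
  MM1; 3 Hz keeps ~97% of each line's energy within 0.1 ppm.
* **MRSI phantoms**: square grids (64 x 64 default; 32 x 32 for desk-scale
  acceptance runs) with an elliptical brain mask, a cortical GM ribbon,
  central CSF, per-voxel amplitudes `intercept + slope * gmf` per basis
  component (Glu/tCr higher in GM; most MM rising with GM, MM7 flat,
  MM8 higher in WM), a two-voxel lipid rim (0.9/1.3 ppm Lorentzians,
  0.15 ppm wide, 10x the MM1 amplitude scale), a smooth ±1 Hz
  left-right frequency-offset field, and white complex noise set so the
  best NAA voxel reaches a target spectral SNR (40 in the standard
  conditions).

What the phantom does *not* emulate: J-coupling multiplet structure,
B0-inhomogeneity line-broadening variation, susceptibility-induced
non-ideal lineshapes, motion, and chemical-shift displacement. Passing
tests therefore demonstrate correctness of the estimation machinery
under the stated model, not robustness to every in vivo artifact.

Problem sizes used by the shipped analyses: parameterization recovery
over 20 noise seeds at SNR 50; ratio-prior stabilization over 50 seeds
at SNR 40; CRLB calibration over 200 replicates at SNR 30; the grid
pipeline on a 32 x 32 phantom (616 brain voxels) at SNR 40.

## Numerical choices and degenerate inputs

* Sub-bin peak localization by three-point parabola (the native grid is
  2.93 Hz per bin); FWHM by linear interpolation of the half-height
  crossings; "peak unresolved" is an error, not a silent NA.
* Hankel-SVD rank deficiency returns fewer components with a warning;
  growing components (negative damping) are kept but flagged.
* Near-collinear basis pairs (Cr/PCr, GPC/PCh) are handled by a
  pseudo-inverse fallback inside the active-set solver; their sums are
  the quantities with meaningful CRLBs.
* The no-extra-broadening boundary is explicitly tested after the outer
  optimization (the optimum frequently sits at 0 Hz and quasi-Newton
  iterations approach bounds slowly).
* All generators are pure functions of (parameters, seed) and restore
  the caller's RNG state.

## Known limitations

* The Hankel-SVD center bias for weak broad peaks described above.
* Interior-voxel MM medians run at ~12% error at SNR 40 — close to the
  information limit for 9 broad overlapping components under a free
  spline baseline; the soft priors are what keep them there (unpriored
  individual MM amplitudes scatter by ~100%).
* Amplitudes are institutional units throughout; water-scaling absolute
  quantification is out of scope.
* Single-slice 2D only; no partial-volume correction of amplitudes.
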