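---
title: "Models and methods behind lcophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lcophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcophys)
```

`lcophys` analyses the photophysics of amyloid-binding fluorescent
ligands: TCSPC decay fitting, relative quantum yield, equilibrium binding
with per-species brightness, emission-spectrum processing, and FLIM
region-of-interest analysis. This vignette documents the models, their
assumptions, the defaults that matter, and the numerical choices — in
enough detail that a user can judge when the methods apply to their data.

Units are fixed package-wide: times in picoseconds, wavelengths in
nanometres, concentrations in nanomolar. Nanoseconds appear only at
presentation level (FLIM histograms and rendering).

## TCSPC reconvolution fitting

A photon-counting histogram records the true decay convolved with the
instrument response function (IRF). The forward model is

$$ m_k = s \left[\mathrm{IRF} * \sum_{i=1}^{2}
   \frac{B_i}{100} e^{-t/\tau_i}\right]_k + b, $$

with channel times taken at bin centres. `fit_biexponential()` minimizes
the weighted residual sum with Neyman weights $1/\max(c_k, 1)$ — the
classic choice of TCSPC instrument software, where the per-channel
variance is estimated by the observed count. Poisson maximum-likelihood
fitting is deliberately out of scope: at the count levels the package
targets (≥ a few hundred counts in the peak) the weighted-LS and MLE
estimates are practically indistinguishable, and weighted LS keeps the
reduced chi-square interpretable.

Choices that matter:

- **Parameterization.** Lifetimes and the scale are fitted as logarithms
  and the amplitude split as a logit, which enforces $\tau_i > 0$ and
  $B_1 + B_2 = 100$ without constrained optimization. Components are
  reordered post-fit so $\tau_1 < \tau_2$ and amplitudes are reported as
  percentages.
- **Fit window.** Defaults to `[peak channel − 5, last channel]`. The
  rising edge carries most of the IRF-shift information; including a few
  pre-peak channels stabilizes the reconvolution without making the fit
  hostage to background modelling far before the pulse. The window is an
  argument because instruments and conventions differ.
- **Restarts.** On non-convergence the fit restarts up to three times
  from jittered initial lifetimes. The jitter factors come from a fixed
  internal stream (and the caller's RNG state is restored), so fits are
  deterministic.
- **Averages.** Both the amplitude-weighted mean
  $\sum B_i\tau_i / \sum B_i$ and the intensity-weighted mean
  $\sum B_i\tau_i^2 / \sum B_i\tau_i$ are reported; the latter weights
  each component by its photon contribution and is never smaller
  (Cauchy–Schwarz), with equality only for coinciding components.

Convolution is computed as a causal discrete convolution via a
zero-padded FFT at a power-of-two length; an IRF shift is applied by
linear interpolation on the channel grid before convolving.

## Relative quantum yield

The gradient method regresses integrated emission on absorbance across a
dilution series and compares slopes against a reference fluorophore:
$\Phi = \Phi_\mathrm{ref} (m_s/m_\mathrm{ref}) (n_s^2/n_\mathrm{ref}^2)$.
Two design decisions:

- The intercept is estimated, not forced through the origin — plate and
  cuvette offsets are real, and the slope is what carries the physics.
- The refractive-index correction defaults to no correction
  (`n_sample = n_ref = 1`) and is applied only when indices are supplied
  (e.g. n(PBS) = 1.334, n(MeOH) = 1.329, n(EtOH) = 1.361), since matched
  solvents cancel it exactly.

The reference quantum yield is a required argument with no default: it
belongs to the user's calibration, not to the package. A series with any
absorbance above 0.2 triggers a warning — outside the optically dilute
regime, inner-filter effects bias the slope downward.

## Ligand-depletion binding models

At the concentrations typical of fibril titrations, bound ligand is a
large fraction of total ligand, so the free≈total approximation fails and
mass balance must be solved explicitly.

- **One site.** The closed-form root of the depletion quadratic is
  evaluated as $B = 2PL / ((P{+}L{+}K_d) + \sqrt{(P{+}L{+}K_d)^2 - 4PL})$.
  This algebraically equivalent form avoids catastrophic cancellation
  when $K_d \ll P, L$ (the subtractive form loses all significant digits
  exactly in the tight-binding regime of interest). It also degrades
  gracefully to the stoichiometric limit $B = \min(P, L)$ at $K_d = 0$.
- **Two sites.** The free-ligand conservation equation
  $L + S_1 L/(L+K_{d1}) + S_2 L/(L+K_{d2}) = L_\mathrm{tot}$ has a
  strictly increasing left side, so the root on $[0, L_\mathrm{tot}]$ is
  unique; it is found by `uniroot` with a tolerance of
  $10^{-12}\max(L_\mathrm{tot},1)$ followed by one Newton polish step.
  Each site class then fills independently as
  $B_s = S_s L/(L+K_{ds})$.
- **Brightness weighting.** The predicted signal is
  $c(\Phi_\mathrm{free} L_\mathrm{free} + \Phi_1 B_1 + \Phi_2 B_2)$, a
  single instrument scale times quantum-yield-weighted concentrations.
  Per-plate scales are a non-goal; one multiplicative scale is shared
  across a titration.
- **Stoichiometry.** Site densities default to one binding site per
  protein monomer per site class ($S$ = monomer concentration). Fibril
  stoichiometry is genuinely unknown in general, so this is exposed as an
  ordinary parameter rather than buried as a constant.
- **Fitting.** `fit_binding()` fits $K_d$, site densities and scale on
  the log scale (positivity without constraints) by Levenberg–Marquardt;
  quantum yields are fitted raw when freed. An identifiability warning
  fires when the log-scale standard error of a fitted parameter spans
  more than a decade (or is unestimable) — the typical symptom of a
  titration with no curvature, where all concentrations sit far above
  saturation.

`population_fractions()` reports the free/bound composition of total
ligand along a titration; zero-ligand rows are undefined and returned as
`NA` rather than silently dropped.

## Spectral processing

All integration is trapezoidal on the native wavelength grid. The
plate-reader grid the package targets is coarse (5 nm); resampling or
spline interpolation would invent data, so none is performed — a grid
mismatch between sample and blank is an error, not an interpolation.

Negative differences after blank subtraction are floored at zero by
default because area normalization requires non-negative mass; the raw
differences are retrievable with `floor = FALSE`. Peak finding smooths
with a Savitzky–Golay filter (window 15 nm, order 2 by default) purely
to *locate* maxima; reported intensities are always taken from the
unsmoothed spectrum. Replicate aggregation uses the sample standard
deviation (n − 1).

## FLIM ROI analysis

Per-pixel lifetimes use the centroid ("fast lifetime") estimator: mean
photon arrival time minus the IRF centroid. At realistic per-pixel photon
counts a full per-pixel biexponential fit is noise-dominated, while the
centroid is photon-efficient and unbiased for a single-exponential decay.
One subtlety is handled exactly: an exponential sampled on a uniform grid
of width $\Delta$ has discrete mean $\Delta/(e^{\Delta/\tau}-1) \approx
\tau - \Delta/2$, so the estimator inverts this relation,
$\tau = \Delta / \log(1 + \Delta/m)$, removing the half-channel bias
rather than approximating it. Pixels below `min_photons` (default 100)
are undefined (`NA`) and excluded downstream.

ROI lifetime histograms are area-normalized (default bin width 0.02 ns)
so that distributions from ROIs of different sizes are comparable, then
summarized by a least-squares Gaussian fit. The width is reported both as
$\sigma$ and as FWHM $= 2\sqrt{2\ln 2}\,\sigma$, because conventions
differ between instruments and publications and the two are easily
conflated. If the fit cannot converge — or fewer than 5 bins are
occupied — a moment-based fallback (weighted mean, $2.3548\times$
weighted sd) is returned with an explicit `fallback = TRUE` flag that
propagates into result files.

False-color rendering maps lifetimes linearly onto a perceptually uniform
colormap (viridis, 256 levels) over a fixed display range, 0–2 ns by
default; undefined pixels render black, and the mapping is invertible up
to one quantization step.

## Synthetic-data generators

The generators produce every input class with the statistical structure
the analysis assumes:

- **Decays/FLIM:** independent Poisson counts per channel around the
  IRF-convolved model curve — given a pixel's Poisson-distributed total,
  channels are filled multinomially, which yields exactly independent
  Poisson channel counts.
- **Plate-reader spectra:** Gaussian bands plus additive Gaussian noise
  clipped at zero.
- **Titrations:** multiplicative noise, signal × (1 + ε) with
  ε ~ N(0, CV), because plate-reader error scales with signal.
- **FLIM scenes:** disjoint labelled regions, each with its own decay
  parameters and optionally a Gaussian pixel-to-pixel lifetime
  dispersion (`tau_jitter_sd`) emulating heterogeneous binding
  environments.

Seeds are explicit arguments everywhere, fixed seeds give bit-identical
outputs, and the caller's global RNG state is preserved.

Defaults were chosen once for plausibility, since the source instruments
are not parameterized publicly: Gaussian IRF of 100 ps FWHM centred at
500 ps, 7 ps channels × 4096 for cuvette TCSPC, 25 ps channels × 512 for
FLIM (the window must span ≳ 12 lifetimes so that truncation bias on the
centroid estimator is negligible), 10⁴ peak counts, and — for the
recovery studies — 2 × 10⁴ expected photons per FLIM pixel with a
pixel-to-pixel lifetime dispersion of 0.12 ns FWHM in all lifetime
regimes, with 10⁴-pixel ROIs. Test fits on cuvette-style decays use a
1024 × 14 ps grid to keep suites fast; the acceptance checks use the
full default grid.

What passing tests on synthetic data do **not** show: correctness under
detector afterpulsing, pile-up at high count rates, non-Gaussian IRFs
(the generator is Gaussian-only), scattered-light contamination,
wavelength-dependent detector response, or spatial correlations between
pixels. Real instrument data violate all of these to some degree; the
synthetic suite validates the estimators under their stated assumptions,
not the assumptions themselves.

## Known limitations

- Biexponential models only; triple-exponential decays must be handled
  by the user via repeated two-component analysis or are out of scope.
- The per-pixel centroid lifetime is biased for genuinely
  multi-exponential pixels (it estimates the intensity-weighted mean of
  the mixture, not either component).
- No reader for proprietary instrument formats; conversion to the
  documented delimited-text and TIFF layouts is upstream of this
  package.
- The equilibrium binding models assume a well-mixed solution at
  equilibrium with identical independent sites within each class; no
  cooperativity, kinetics, or ligand aggregation.
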