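# lcophys

Quantitative photophysics of amyloid-binding fluorescent ligands in R.

Luminescent conjugated oligothiophenes (LCOs) such as h-FTAA report on
amyloid structure through shifts in their emission spectrum, fluorescence
lifetime and brightness when they bind the cross-β architecture of protein
fibrils. Characterizing a probe therefore requires several coupled
analyses: fitting time-correlated single photon counting (TCSPC) decay
histograms, determining relative quantum yields, modelling equilibrium
binding titrations, and analysing fluorescence lifetime imaging (FLIM)
data per region of interest. `lcophys` implements this pipeline as a set
of composable, tested functions, together with seeded synthetic-data
generators that emulate every input class — so the entire analysis can be
exercised and validated without access to instrument data.

## What it computes

**TCSPC decay fitting.** Measured decays are the true decay blurred by the
instrument response function (IRF). `fit_biexponential()` fits the
iterative-reconvolution model

&nbsp;&nbsp;&nbsp;&nbsp;*m(t) = s · (IRF ∗ Σᵢ (Bᵢ/100) e^(−t/τᵢ)) + bg*

by weighted least squares (Neyman weights 1/max(c,1), Levenberg–Marquardt)
and reports both standard lifetime averages:

- amplitude-weighted: ⟨τ⟩ₐ = Σ Bᵢτᵢ / Σ Bᵢ
- intensity-weighted: ⟨τ⟩ᵢ = Σ Bᵢτᵢ² / Σ Bᵢτᵢ (always ≥ ⟨τ⟩ₐ)

**Relative quantum yield.** The gradient method: an OLS slope *m* of
integrated emission versus absorbance per dilution series, and
Φ = Φ_ref · (m_s/m_ref) · (n_s²/n_ref²), with first-order error
propagation (`fit_gradient()`, `relative_qy()`).

**Ligand-depletion binding models.** One-site equilibria are solved in the
numerically stable closed form
B = 2PL / ((P+L+K_d) + √((P+L+K_d)² − 4PL)); two-site equilibria solve
L + S₁L/(L+K_d1) + S₂L/(L+K_d2) = L_tot by bracketed root finding. The
predicted fluorescence is brightness-weighted per species,
S = c·(Φ_free·L_free + Φ₁B₁ + Φ₂B₂), so bright bound states and dim free
ligand are modelled jointly (`solve_one_site()`, `solve_two_site()`,
`simulate_curve()`, `fit_binding()`, `population_fractions()`).

**Spectral processing.** Blank subtraction, trapezoidal area
normalization, Savitzky–Golay peak finding and replicate mean ± sd bands
(`subtract_blank()`, `area_normalize()`, `find_peaks()`,
`aggregate_replicates()`, `integrate_spectrum()`).

**FLIM ROI analysis.** Per-pixel "fast" (centroid) lifetimes with exact
correction of the channel-discretization bias, area-normalized ROI
lifetime histograms, Gaussian centre/FWHM fits and false-color map
rendering (`pixel_lifetimes()`, `roi_histogram()`, `fit_gaussian()`,
`render_false_color()`).

**Synthetic data.** `gen_irf()`, `gen_decay()`, `gen_emission_spectrum()`,
`gen_binding_dataset()` and `gen_flim_image()` generate every input with
the statistical structure the analysis assumes (Poisson photon counting,
multiplicative plate-reader noise, Gaussian pixel-to-pixel lifetime
dispersion), with explicit seeds.

## Worked example

Simulate a two-component decay in the aqueous-buffer regime
(τ = 332/788 ps, B = 88/12 %), blur it with a 100 ps FWHM Gaussian IRF,
add Poisson noise at 10⁴ peak counts, and refit:

```r
library(lcophys)

irf   <- gen_irf(irf_spec(center = 500, fwhm = 100), 1024, 14)
trace <- gen_decay(decay_params(tau = c(332, 788), amp = c(88, 12)), irf,
                   peak_counts = 1e4, seed = 1)
fit_biexponential(trace)
#> <decay_fit> biexponential reconvolution fit
#>   tau1 = 327.4 +/- 2 ps   B1 = 85.7%
#>   tau2 = 738.4 +/- 7.1 ps   B2 = 14.3%
#>   tau_amp = 386.3 ps, tau_int = 440 ps, chi2_red = 0.5141
```

Both lifetimes are recovered within a few percent and the
intensity-weighted average rounds to 440 ps, the value expected for this
parameter regime. The brightness-weighted two-site depletion model
(K_d1 = 100 nM, K_d2 = 300 nM, 1000 nM of each site class, bound quantum
yields 40 %/20 % against 6 % free):

```r
solve_two_site(1000, 1000, 1000, 100, 300)
#> <species_populations> free = 130.5, bound1 = 566.2, bound2 = 303.2 nM

p  <- binding_params(kd1 = 100, sites1 = 1000, qy_free = 0.06,
                     qy_site1 = 0.40, kd2 = 300, sites2 = 1000,
                     qy_site2 = 0.20)
ds <- simulate_curve(p, 1000)
ds$signal[1, 1] / ds$ligand_only_signal[1]
#> [1] 4.92
```

At 1000 nM total ligand the model predicts a ~5-fold fluorescence
enhancement over free ligand alone — the brightness gain on fibril
binding.

A command-line surface over the same functions is available via
`run_command()` (see `inst/scripts/lcophys`), e.g.
`lcophys simulate decay --tau 332,788 --amp 88,12 --seed 1 --out d.csv`.

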