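# pyroflume

Analysis pipeline for paired control-versus-treatment in-stream flume
experiments on pyrogenic carbon (PyC, wildfire charcoal) inputs to
rivers — for stream ecologists and biogeochemists who need the full
chain from raw flume time series and fluorescence landscapes to
treatment effect sizes, and for methodologists who want every stage
testable against synthetic data with known truth.

## What it computes

* **Treatment effects from repeated measures.** Each flume's time
  series is modelled as a Gaussian process with linear mean
  `β0 + βT·T` (T = treatment indicator) and within-flume covariance
  `k(t_i, t_j) = α² exp(−(t_i−t_j)²/(2ρ²)) + σ² δ_ij`; flumes are
  independent and share one hyperparameter set. Bayesian calibration
  uses an affine-invariant ensemble sampler with split-R̂ diagnostics
  (fast Laplace mode for simulation studies), reporting the effect
  posterior mean ± SD with an equal-tailed 90% credible interval, plus
  an OLS no-time-dependence comparison fit.
* **DOM chemometrics.** SUVA254 from absorbance spectra; Milli-Q blank
  subtraction; Rayleigh scatter masking (`|em−ex| ≤ w`, `|em−2ex| ≤ w`);
  nonnegative PARAFAC of EEM cubes by missing-data-aware alternating
  least squares; leverage-based outlier flagging; component peak
  positions; total and DOC-normalized fluorescence.
* **Enzyme stoichiometry.** The six biomass-independent activity ratio
  indices (Xyl/Glu, (Glu+Xyl)/Cbh, Glu/Pep, Glu/Pox "recalcitrance
  index", Pep/Pho, NAG/Pox) with paired (df = n−1) or Welch t tests.
* **Leaching mass balance.** Field DOC release `m = Q·t·ΔDOC`, per-gram
  normalization, and the particulate estimate
  `POC = TOC_lab − DOC_flume`.
* **Seeded synthetic generators** for flume series (the GP model
  itself), EEM cubes (trilinear Gaussian-peaked fluorophores, optional
  scatter ridges) and enzyme plates (lognormal), so every downstream
  stage has a testable ground truth.

## Worked example

Simulate the default DOC world (5 + 5 flumes at 1–8 h, baseline
3.32 mg/L, planted effect +0.40 mg/L), fit the GP, and push the
modelled effect through the mass balance:

```r
library(pyroflume)
dat  <- simulate_flume_series(default_designs()$doc, seed = 42)
post <- fit_gp(dat, seed = 7)
print(post)
#> <gp_posterior> response 'doc' (mcmc, 20000 draws)
#>   treatment effect: 0.294 +/- 0.175, 90% CI [0.006, 0.580]
#>   max split-Rhat 1.017; mean acceptance 0.54; converged: TRUE

predict_group_means(post)
#>       group     mean        sd     q05      q95
#> 1   control 3.371940 0.1258356 3.16738 3.572713
#> 2 treatment 3.665576 0.1254781 3.46744 3.872981

mass_balance_summary(flume_hydraulics(delta_doc = post$effect_mean))
#>            quantity       value      units
#> 1 throughput_volume 225.6000000          L
#> 2  leached_doc_mass  66.2443726         mg
#> 3 doc_release_per_g   0.2944194 mg C/g PyC
#> 4     toc_lab_per_g   0.8400000 mg C/g PyC
#> 5         poc_per_g   0.5455806 mg C/g PyC
```

Reading: this particular simulated campaign recovers a +0.29 mg/L DOC
effect (true planted value 0.40, posterior SD 0.17 — one draw of a
noisy 10-flume experiment), control/treatment predicted means of
3.37/3.67 mg/L, and 225.6 L of water per flume over 8 h carrying an
estimated 66 mg of leached DOC (0.29 mg C per g of charcoal). With the
study's printed inputs (ΔDOC = 0.40) the same balance gives
0.40 mg C/g dissolved and 0.44 mg C/g particulate release.

A 4-component PARAFAC on 30 synthetic EEMs planted at the study's
component peaks:

```r
cube  <- simulate_eems(eem_design(), seed = 1)
model <- fit_parafac(cube, n_components = 4, n_starts = 10, seed = 2)
component_maxima(model)   # peaks recovered within one 5 nm grid step
```

End-to-end run (synthetic generation → GP fits for DOC/SUVA254/pH →
PARAFAC → enzyme tests → mass balance, all CSV + run log):

```r
run_full_analysis(default_run_config(seed = 1), outdir = "run1")
```

or from the shell: `inst/cli/pyroflume reproduce --seed 1 --out run1`
(subcommands: `simulate`, `fit-gp`, `parafac`, `suva`, `enzyme-ratios`,
`mass-balance`, `reproduce`).

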