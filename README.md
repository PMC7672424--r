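# gqfret

Single-molecule FRET (smFRET) burst analysis for resolving the
conformational ensemble of multimeric G-quadruplex DNA and quantifying
ligand-driven population shifts.

Telomeric G-rich repeats fold into G-quadruplexes, and longer repeats carry
several quadruplex units in tandem. A dimeric construct labelled with a
donor (FAM) and acceptor (Cy5) dye reports its global conformation through
the FRET efficiency of freely diffusing molecules crossing a confocal spot.
`gqfret` implements the complete analysis chain for such an experiment:

1. **Photon-stream simulation** (`sim_config`, `simulate_photon_stream`,
   `simulate_titration`) — diffusing-molecule bursts over a Poisson
   background with pulsed interleaved excitation (PIE, 32 MHz): each burst
   draws a conformational state with true efficiency *E*, its
   donor-excitation photons split donor/acceptor binomially with
   probability *E*, and a configurable fraction falls in the
   acceptor-excitation window for stoichiometry.
2. **Burst search** (`search_bursts`) — photon traces binned at 1 ms,
   runs of bins at or above a counts/bin threshold (customary range 4–9)
   form candidate bursts, and bursts below 25 total photons are discarded.
3. **FRET efficiency and stoichiometry** (`corrected_E`, `stoichiometry`,
   `filter_dual_label`) — standard PIE/ALEX correction algebra:
   background, donor leakage α, acceptor direct excitation δ and detection
   factor γ, reducing to the proximity ratio n_DA/(n_DA+n_DD) at defaults.
4. **Species decomposition** (`fit_mixture`) — the burst *E* distribution is
   fit as a K-component Gaussian mixture by expectation–maximization with
   deterministic quantile initialization; `select_components` chooses K by
   BIC, `population_fractions` labels species low→high FRET.
5. **Binding isotherm** (`build_titration`, `fit_kd`) — the high-FRET
   population fraction f(L) along a ligand titration is fit with the
   conformational-selection law
   f(L) = f₀ + (f∞ − f₀)·L/(K_D + L),
   by weighted least squares with a deterministic multistart (a
   ligand-depletion-corrected variant is available).
6. **Melting curves** (`fit_tm`, `delta_tm`) — Boltzmann sigmoid fits of
   thermal denaturation curves (e.g. ellipticity at 295 nm), giving the
   midpoint Tm and the ligand-induced stabilization ΔTm.

`run_pipeline` ties the stages together reproducibly (seeded, with a config
hash stamped into every output file).

## Worked example

```r
library(gqfret)

# a 2-state ensemble: species at E = 0.6 and 0.8, populations 38% / 62%
cfg <- sim_config(duration = 30, burst_rate = 30, seed = 91)
stream <- simulate_photon_stream(cfg)
bursts <- search_bursts(stream, burst_search_params(threshold = 5))
E <- corrected_E(bursts, correction_factors(bg_rate_dd = 200,
                                            bg_rate_da = 200,
                                            bg_rate_aa = 200))
fit <- fit_mixture(E, k = 2)
fit
#> Gaussian mixture of 2 FRET species (n = 585 bursts)
#>           mean_E sigma weight
#> low-FRET   0.610 0.068  0.392
#> high-FRET  0.802 0.054  0.608
#> logLik 512.24, BIC -992.62, 63 EM iterations
```

The two recovered species sit at the configured efficiencies and the
high-FRET population (61% here, from ~600 bursts) estimates the configured
62%. A titration adds the binding constant:

```r
res <- run_pipeline(pipeline_config(
  sim = sim_config(duration = 100, burst_rate = 30, seed = 501),
  binding = binding_params(kd = 0.53, f0 = 0.62, f_inf = 1.0),
  concs = c(0, 0.125, 0.25, 0.5, 1, 2, 4)))
res$binding
#> Conformational-selection binding fit (hyperbolic, 7 points)
#>   Kd    = 0.584 uM (SE 0.074)
#>   f0    = 0.601 (SE 0.0086)
#>   f_inf = 0.992 (SE 0.013)
#>   weighted RSS = 0.706
```

The fitted K_D (0.58 μM from ~2000 bursts per point) recovers the simulated
0.53 μM within the expected stochastic scatter. Melting stabilization:

```r
apo   <- fit_tm(simulate_melting_curve(60,   3, noise_sd = 0))
bound <- fit_tm(simulate_melting_curve(74.6, 3, noise_sd = 0))
delta_tm(bound, apo)
#> [1] 14.6
```

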