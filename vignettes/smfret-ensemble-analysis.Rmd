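---
title: "Resolving G-quadruplex conformational ensembles from smFRET bursts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving G-quadruplex conformational ensembles from smFRET bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqfret)
```

## The experiment this package models

A multimeric G-quadruplex — here a dimer of human-telomeric quadruplex
units joined by a TTA linker — is labelled with a FRET donor (FAM) at the
5′ end and an acceptor (Cy5) at the 3′ end. At ~100 pM, individual
molecules diffuse through a confocal excitation spot and emit a brief
burst of photons. The distance between the dye ends, and therefore the
FRET efficiency of each burst, reports the fold of the molecule, so the
per-burst efficiency distribution resolves coexisting conformers that bulk
measurements average away. Pulsed interleaved excitation (PIE) at 32 MHz
adds a direct acceptor-excitation window within each sync period, giving a
per-burst stoichiometry that can reject singly-labelled molecules.

A ligand that binds one conformer preferentially enriches it without
shifting its efficiency — conformational selection. Tracing the high-FRET
population against ligand concentration therefore yields a binding
isotherm and a dissociation constant. A parallel thermal-melting readout
(ellipticity at 295 nm versus temperature) measures the stabilization ΔTm
the ligand confers.

## The synthetic photon-stream generator

Raw confocal photon data for such experiments are rarely deposited, so the
package includes a generator (`simulate_photon_stream`) that emulates the
acquisition and makes every downstream stage testable end to end:

* **Burst arrivals** are Poisson with rate `burst_rate`; each burst's
  photons are spread uniformly over an exponential-duration window of mean
  1 ms. The burst search operates on 1 ms bins, so finer within-burst
  kinetics would be unobservable anyway; a diffusion model would add
  parameters without adding testable structure.
* **Burst sizes** are geometric with mean `burst_size_mean` (default 60
  photons), heavy-tailed like real diffusing-molecule transits while
  remaining simple enough for closed-form checks.
* **States**: each burst draws a conformational state from the configured
  weights; its donor-window photons land in the acceptor channel with
  probability equal to the state's true efficiency (binomial partition),
  and a binomial `aa_fraction` (default 0.25) of its photons fall in the
  acceptor-excitation window. The default 0.25 gives a usable
  stoichiometry signal without attempting to model laser powers and
  detection yields.
* **Background** is Poisson per channel over the whole acquisition
  (default 200 counts/s per channel, a typical clean-buffer rate).
* **Seeding**: one master seed; titration points derive per-stream seeds
  deterministically from (master, index), so a series is reproducible as a
  whole.

What the generator does *not* emulate: photophysics (blinking,
photobleaching — suppressed chemically in the modelled experiment),
diffusion-shaped burst intensity profiles, interphoton-time structure
within the sync period, and detector artifacts (afterpulsing, dead time).
Passing tests therefore demonstrate the correctness of the analysis chain
on idealized streams with realistic counting statistics — not robustness
to every instrumental pathology of real data.

The default two-state ensemble places species at E = 0.6 and 0.8 with
weights 0.38/0.62, the resolved apo ensemble of the dimeric construct;
ligand response follows the 1:1 population-shift law below.

## Burst search

`search_bursts` reproduces the classic binned search: counts in half-open
1 ms bins, a candidate burst being a maximal run of bins at or above
`threshold` counts/bin (customary range 4–9, default 5; values outside the
range warn but run), retained if it holds at least `min_photons` = 25
photons over all channels and excitation windows. A photon exactly on a
bin boundary belongs to the later bin — the half-open convention removes
any ambiguity. Adjacent above-threshold bins merge with no gap tolerance
by default (`gap_tolerance` is exposed for bridging single quiet bins).
The implementation is vectorized but is verified, in the test suite,
against a deliberately naive enumerator on hundreds of random small
streams.

## FRET efficiency, stoichiometry, and their corrections

With background rates b and burst duration τ, the corrected acceptor
signal is

F_A = (n_DA − b_DA·τ) − α(n_DD − b_DD·τ) − δ(n_AA − b_AA·τ),

and E = F_A / (F_A + γ(n_DD − b_DD·τ)). Defaults (γ = 1, α = δ = 0, zero
background) reduce E to the proximity ratio, because instrument
calibrations are inherently setup-specific user input. E is deliberately
**not clamped** to [0, 1]: shot noise legitimately scatters bursts
slightly outside, and clamping would pile probability mass at the edges
and distort the mixture fit. Bursts whose corrected denominator is
non-positive (background-dominated) are flagged and excluded.
Stoichiometry S = (γF_DD + F_A)/(γF_DD + F_A + F_AA) supports an optional
dual-label gate (default bounds 0.25–0.85) that is **off** unless
explicitly enabled — the modelled analysis does not document an S filter,
so the pipeline does not impose one silently.

## Gaussian-mixture decomposition

`fit_mixture` fits the per-burst E values by maximum likelihood
(expectation–maximization), not least squares on the binned histogram:
binning discards information and forces an arbitrary bin width. The
histogram least-squares backend (`fit_mixture_histogram`) is retained and
the tests assert the two agree on well-separated data.

Numerical choices:

* deterministic initialization — component means at the interior
  k-quantiles, common sigma = pooled SD/k, uniform weights; optional
  seeded random restarts (`init = "random"`);
* convergence at log-likelihood gain < 1e-8 or 500 iterations; the
  likelihood trace is stored and asserted non-decreasing in the tests;
* `sigma_floor` = 1e-3 prevents the singular collapse of a component onto
  a repeated value; a component stuck at the floor with vanishing weight
  is flagged rather than hidden;
* components are reported sorted by mean, so "high-FRET" is always the
  last component regardless of EM's internal ordering;
* `select_components` compares k = 1..k_max by BIC but is never invoked
  implicitly: k = 2 is the default for dimer-ensemble analyses.

### Tracing populations along a titration

Fitting every titration point independently proved unreliable at the
extremes of a titration: when one species exceeds ~90%, the per-state
burst-E distribution — a scale mixture over burst sizes, hence
heavier-tailed than any single Gaussian — tempts an unconstrained
two-component fit into splitting the dominant peak instead of finding the
minor species. Physically, a conformational-selection titration does not
move the species' efficiencies, only their populations. The pipeline
therefore fits means and widths once, on the apo point where both species
are well populated, and then runs weights-only EM (`fixed_means`,
`fixed_sigmas`) at every concentration. Independent per-point fitting
remains available through `fit_mixture` directly.

## The binding isotherm

The high-FRET fraction follows f(L) = f₀ + (f∞ − f₀)·L/(K_D + L),
hyperbolic in *total* ligand: with DNA at ~100 pM and ligand in the
micromolar range, ligand depletion is negligible. A depletion-corrected
form that solves the 1:1 quadratic for free ligand is available
(`model = "quadratic_depletion"`). f∞ is a free parameter rather than
pinned to 1, since a residual low-FRET population can persist at the
highest measured concentration. The least-squares fit weights points by
their burst counts (more bursts, more information; `weighted = FALSE`
disables this) and uses a deterministic multistart over
log10(K_D) ∈ {−2, …, 2} refined by Levenberg–Marquardt, so no RNG enters
the fit. Standard errors come from the fit curvature. A flat series
raises an identifiability error; a dynamic range below 0.05 warns.

## Melting curves

`fit_tm` fits the Boltzmann sigmoid
s(T) = low + (high − low)/(1 + exp((Tm − T)/w)) by Levenberg–Marquardt
from a deterministic multistart (midpoint candidates from the smoothed
derivative extremum and the temperature quartiles; width candidates
range/40, range/20, range/8), keeping the best residual sum of squares.
Baselines are horizontal by default; `sloped_baselines = TRUE` adds linear
folded/unfolded slopes. The derivative-extremum midpoint is always
computed as an independent cross-check and a disagreement beyond 1 °C
warns — on noiseless curves the two agree, on broad noisy transitions the
derivative method is the less reliable of the pair. A fitted amplitude
within 3 residual SDs raises a no-transition error rather than returning
a meaningless midpoint. ΔTm is a plain difference of fitted midpoints and
may be negative (destabilization).

## Problem sizes and reproducibility

The package's own verification uses ensembles of 5000 burst E values for
mixture recovery (recovering means within ±0.02 and weights within ±5
percentage points), 7-point titrations at roughly 2000–3000 detected
bursts per point for the photon-level K_D recovery (within ±30%), and
1 °C-step melting curves over 4–95 °C for Tm (±0.5 °C under 2% noise).
These sizes match what a one-to-two-hour confocal acquisition per
titration point realistically yields. Every stochastic stage is seeded;
`run_pipeline` hashes its configuration into every output file so a
result bundle is traceable to the exact settings that produced it.

## Known limitations

* The mixture model assumes Gaussian species; shot-noise-limited
  distribution analysis (PDA), which would predict the width from burst
  sizes, is out of scope, as are Bayesian mixture inference and global
  multi-dataset fits.
* Correction factors (γ, α, δ) must be supplied by the user; there is no
  self-calibration routine.
* The binding model is strictly 1:1 with no cooperativity (no Hill
  coefficient).
* Melting analysis yields Tm/ΔTm only — no van 't Hoff ΔH/ΔS extraction.
* Photon streams are read from flat CSV; instrument-vendor raw formats
  are not parsed, though the photon table schema (timestamp, channel,
  excitation window) is designed so external converters can feed it.
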