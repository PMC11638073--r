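# mitoflux

Reconstructing the assembly pathway of the human mitochondrial ribosome
from pulse–chase triple-SILAC sucrose-gradient proteomics.

The human mitoribosome is built from 82 nuclear-encoded mitoribosomal
proteins (MRPs) — 30 in the 28S small subunit (mtSSU), 52 in the 39S large
subunit (mtLSU) — assembled onto mitochondrially encoded rRNAs. `mitoflux`
is for proteomics and systems-biology groups who run pulse–chase SILAC
experiments over density-gradient fractions and want to turn the resulting
H/M/L intensity grids into an assembly pathway: which proteins preassemble
into modules, in which order the modules join, and which kinetic steps
control mature-subunit abundance.

The package implements, end to end:

* **Turnover models** — one-state (exponential) and two-state
  (nonexponential, complex-protected) protein turnover under piecewise
  exponential cell growth,
  `dA/dt = p C(t) − (k_a + k_ab)A`, `dB/dt = k_ab A − k_b B`,
  with likelihood-ratio model selection, shared growth-rate inference from
  a filtered stable-protein pool, and exponential-decay half-life fits
  (`t½ = ln 2 / k`) for transcription-block time courses.
* **Gradient normalization** — spike-in (H/L, M/L) normalization against a
  purified-monosome standard, steady-state normalization per fraction,
  scaling to the mature-subunit reference fraction, detection filtering and
  steady-state abundances `q`.
* **Flux model** — per-protein Bayesian fit of
  `dH_i/dt = −(k_i + a_i)H_i + a_{i−1}H_{i−1}` across fractions
  (21 structural parameters for mtSSU, 24 for mtLSU), summarised as fluxes
  `f_i = k_i + a_i` with 5–95% posterior bands.
* **Cluster inference** — heterogeneity `H` of candidate modules (mean
  pairwise squared flux and abundance differences over fractions), exhaustive
  enumeration of contact-constrained alternatives, quantile placement, and
  dendrogram distances `d = ((f_mod − f_i)² + (q_mod − q_i)²)/2`.
* **Kinetic assembly model** — mass-action ODEs over the packaged mtSSU
  pathway (30 single species, 17 modules; 111 unknown rates reduced to 64
  by exact steady-state elimination; 112 sampled parameters including the
  noise sd) fit to labeled-pool data by MCMC.
* **Sensitivity analysis** — median terminal-abundance fold change under
  multiplicative perturbation of each free rate over `x ∈ [1e-4, 1e4]`,
  with enhancing / inhibiting / nonsensitive classification.
* **Synthetic data** — generators for all three experimental designs with
  multiplicative log-normal noise and missingness, so everything above runs
  and is tested without the deposited raw data.

MCMC uses either an in-package differential-evolution ensemble sampler with
snooker updates (`demc_sample()`) or an adaptive Metropolis sampler
(`am_sample()`, default for the high-dimensional fits); convergence is
checked with the Gelman–Rubin r-hat.

## Worked example

Build the packaged mtSSU model, simulate a gradient-chase experiment,
normalize it, and fit one protein's fluxes:

```r
library(mitoflux)
library(dplyr)

pathway  <- load_pathway(mitoflux_example("mtssu_pathway.yaml"))
contacts <- load_contact_matrix(mitoflux_example("contact_mtssu_synthetic.tsv"))
build_model(pathway)
#> Mass-action assembly model: 30 single species, 17 modules
#>   unknown rates: 111 | free after steady-state elimination: 64
#>   sampled parameters (free rates + ICs + sd): 112
neighbors(contacts, "mS23")
#> [1] "bS1m"  "bS6m"  "bS18m" "uS2m"  "uS5m"

truth <- default_gradient_truth(pathway, seed = 1)
sim <- simulate_gradient_chase(
  simulation_spec("gradient_chase", noise_cv = 0.05, seed = 1),
  pathway, truth)
norm <- sim$data |>
  normalize_to_standard(quiet = TRUE) |>
  steady_state_normalize() |>
  scale_to_subunit(pathway$species$id[pathway$species$kind == "protein"],
                   "mtSSU")

fit <- fit_flux(filter(norm, protein == "mS23") |> select(-protein),
                subunit = "mtSSU", n_iter = 30000, seed = 1)
summarize_flux(fit)
#> # A tibble: 5 × 4
#>   fraction f_median   f_lo   f_hi
#>      <int>    <dbl>  <dbl>  <dbl>
#> 1        1   0.501  0.411  0.614
#> 2        2   0.591  0.417  0.919
#> 3        3   0.427  0.270  0.783
#> 4        4   0.733  0.564  1.25
#> 5        7   0.0188 0.0123 0.0350
```

mS23 exchanges label quickly in the light fractions (fluxes ≈ 0.4–0.7 h⁻¹:
free pools and early modules turn over in a couple of hours) but very
slowly in fraction 7 (f ≈ 0.02 h⁻¹), where it sits inside the stable mature
small subunit; its steady-state abundance there is ≈ 0.035 relative to one
mature subunit. Fractions 5–6 fail the robust-detection filter for this
protein and are reported absent rather than zero.

Half-life of an rRNA-dependent species after a transcription block:

```r
dec <- simulate_etbr_decay(
  simulation_spec("etbr_decay", noise_cv = 0.1, seed = 2), k = log(2) / 15)
fit_decay(dec, seed = 2)
#> Exponential decay fit: k = 0.04438 per h;  t1/2 = 15.62 h
```

`run_pipeline()` chains normalize → flux → cluster (→ kinetic →
sensitivity) and writes plain TSV/JSON artifacts plus a checksum manifest;
a fixed seed reproduces the manifest bit-identically.

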