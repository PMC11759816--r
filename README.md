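# otogeo

Otolith-chemistry inference of fish nursery origins and ontogenetic habitat
shifts, built for stock-identification studies of long-lived demersal fish
(the motivating system is an Antarctic notothenioid sampled as adults). From
LA-ICPMS element:Ca transects and nuclear/edge stable isotopes, the package

1. **dates habitat shifts** — the Barry–Hartigan product-partition model on
   Sr:Ca and Ba:Ca profiles: given a partition of a transect into `b` blocks
   of constant mean, the data density is proportional to
   `w^((b-1)/2) / (W + wB)^((n-1)/2)` (`W`, `B` = within/between-block sums of
   squares), with uniform priors `p ~ U(0, 0.2)` on the change probability and
   `w ~ U(0, 0.2)` on signal-to-noise; a Gibbs sampler (10000 iterations, 5000
   burn-in) gives per-ablation posterior shift probabilities, dated through an
   inverse von Bertalanffy age map;
2. **counts and weighs nursery sources** — EM-fitted Gaussian finite mixtures
   on nuclear signatures under the uneven-volume covariance models
   (`Σ_g = λ_g D_g A_g D_gᵀ`; VVV, VEV, VVE), selected by
   `BIC = 2·loglik − m·log n`, with bootstrap SEs on the mixing proportions;
3. **maps juvenile origins** — a two-stage seawater δ¹⁸O isoscape (penalized
   splines on salinity/temperature/depth + per-stratum exponential-covariance
   kriging of the residuals), pushed through the aragonite fractionation
   relation `δ¹⁸O_oto = 4.64 − 0.21·T + δ¹⁸O_water` with 5000-draw Monte-Carlo
   error propagation, giving per-fish occurrence-probability maps, synoptic
   maps, per-area summaries and top-5% origin regions per mixture cluster.

A synthetic-data generator (`sim_scenario()` / `sim_dataset()`) emulates every
input — mixture-structured signatures, stepped transects, smooth T/S fields,
and a water-δ¹⁸O field whose covariates explain a configurable 61% of
variance — so the whole chain runs and is validated without any downloads.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on the synthetic
world and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # inputs + truth under results/data/
Rscript analysis/02_preprocess.R    # ageing, cohort filter, regions, LOD rule
Rscript analysis/03_ontogeny.R      # stage contrasts + PERMANOVA
Rscript analysis/04_changepoint.R   # shift probabilities and cohort summary
Rscript analysis/05_mixture.R       # BIC grid, proportions, assignments
Rscript analysis/06_isoscape.R      # isoscapes + fractionation bias test
Rscript analysis/07_geolocate.R     # occurrence maps, area summary, top-5%
```

Representative output (seed 1). Stage 4, habitat-shift dating — every
simulated shift recovered within one ablation:

```
cohort habitat-shift summary (ages in years):
 element n_fish n_detected median_age p25_age p75_age
      Ba     37         37       12.7    12.7    14.3
      Sr     37         37       12.7    12.7    14.3
Sr:Ca shift ablation recovered within +-1 for 100% of fish (true median age 12.2 y)
```

Stage 5, source mixtures — two sources selected for both signature sets, as
the generator prescribes (n = 37 retained fish, so the estimated split carries
visible sampling error around the generating 0.74/0.26):

```
elemental signatures: best model G = 2 (VVE), BIC = -907.6
  proportions: 0.59 +- 0.072, 0.41 +- 0.072
isotopic signatures:  best model G = 2 (VVE), BIC = -109.0
  proportions: 0.78 +- 0.063, 0.22 +- 0.063
```

Stage 7, geolocation — occurrence probability decays with depth and the
generating nursery area (A2) ranks first:

```
 area n_cells mean_prob loglik
   A1     100    0.2720  -76.6
   A2     100    0.4278  -41.2
    B     100    0.0971 -152.6
    C     100    0.4091  -46.5
generating dominant area: A2; top-ranked by mean probability: A2
```

`mean_prob` is the two-sided Monte-Carlo tail probability of each fish's
nuclear δ¹⁸O under the cell's expected otolith-δ¹⁸O distribution, averaged
over fish and over the 0–200 m strata; `loglik` is the mean per-cell
`Σ_i ln p_i`. Stage 8 (`analysis/08_deposited_data.R`) reruns the statistical
stages on a user-supplied deposited data table; it is skipped when no path is
given.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance target from scratch
against the installed package — it runs the isotope standardization chain
(`delta_vpdb()`) for a sample whose measured ratio equals the NBS-19 primary
standard on the carbon system — and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/nursery-geolocation.Rmd`) documents the
models, the synthetic world's assumptions, and the design decisions.
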