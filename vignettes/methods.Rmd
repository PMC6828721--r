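---
title: "Probabilistic heavy-metal risk assessment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic heavy-metal risk assessment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

## The problem

Groundwater in fast-industrialising districts is often the only practical
drinking source, and potentially toxic heavy metals (Pb, Cr, Ni, Fe, Mn, Al)
reach wells and boreholes from both geogenic processes (weathering,
dissolution, leaching) and industrial discharge. `aquarisk` implements the
standard US EPA exposure-assessment chain for such settings — dose equations,
hazard quotients, lifetime cancer risk — and makes it probabilistic: instead
of one deterministic risk number per metal, a Monte Carlo simulation
propagates the variability of the concentration and of the exposure factors
into a full risk distribution, reported as percentiles and exceedance
fractions.

The package is organised around a two-district study design — two source
types (boreholes, hand-dug wells), nine locations per source per district,
triplicate measurements, 108 samples from 36 locations — and ships a
synthetic generator for that design, so the whole pipeline is runnable and
testable without any field data.

## Dose and risk model

For a metal concentration $C$ (µg/L) in water, the chronic daily intake via
ingestion and dermal contact are

$$\mathrm{CDI_{ing}} = \frac{C \cdot IR_w \cdot EF_r \cdot ED}{BW \cdot AT_r},
\qquad
\mathrm{CDI_{derm}} = \frac{C \cdot SA \cdot K_p \cdot EF_r \cdot ED \cdot ET
\cdot CF}{BW \cdot AT_r},$$

in µg/kg·day. Non-carcinogenic risk is screened by the hazard quotient
$HQ = \mathrm{CDI}/\mathrm{RfD}$ with the route-specific reference dose;
$HQ > 1$ flags potential risk. Carcinogenic risk uses the oral slope factor:
$\mathrm{LTCR} = \mathrm{CDI_{ing}} \times SF$ with CDI converted to
mg/kg·day at exactly one place in the code (`lifetime_cancer_risk()`), the
single point of unit truth. The conventional acceptability band is
$10^{-6}$–$10^{-4}$.

Averaging time follows the usual convention: $AT_r = ED \times 365$ days for
non-carcinogenic endpoints — which cancels $ED$ algebraically, a property the
test suite asserts numerically — and $AT_r = 70 \times 365$ days (a 70-year
lifetime) for cancer risk. The 70-year carcinogenic averaging time is the
convention back-calculation from the study's adult Ni cancer-risk summaries
is consistent with.

### Toxicity reference values

RfD (µg/kg·day): Al 1000, Cr 1500, Fe 700, Mn 140, Ni 20. Slope factors
((mg/kg·day)$^{-1}$): Ni 1.7, Pb 0.0085, Cr 0.5. The dermal RfD defaults to
the ingestion value unless a dermal-specific entry is configured — the
minimal assumption, made explicit in the configuration rather than buried.

Lead is a special case. The reference study's methods list an RfD of
$1.4\times10^{2}$ µg/kg·day for Pb, but its own hazard-quotient tables are
only consistent with 1.4 µg/kg·day: an adult borehole HQ mean of 1.108 with
concentrations in [11.7, 427.2] µg/L back-calculates to a mean concentration
of about 57 µg/L under RfD 1.4, and to about 5700 µg/L — far outside the
measured range — under RfD 140. `default_toxicity()` therefore defaults to
`pb_rfd = "adjusted"` (1.4) and exposes `"printed"` (140) as a flag; the
discrepancy is documented, not silently resolved.

### Exposure factors

Defaults (`default_exposure_profiles()`): adult — IR 2 L/day, BW 70 kg,
EF 350 days/year, ED 30 years, SA 18 000 cm², ET 0.58 h/day; child — IR 1
L/day, BW 15 kg, ED 6 years, SA 6600 cm², ET 1 h/day; $K_p$ 0.001 cm/h and
CF 0.001 L/cm³ for both. The study's own exposure-factor table is not
published, so these are literature-typical values chosen once to be
self-consistent with the study's reported dose summaries; they are plain
data, overridable per run and serialisable to a key-value config
(`write_exposure_config()`, lossless at 17 significant digits). The child
and adult summaries published by the study are in fact not mutually
consistent with any single factor set (the implied child/adult HQ ratio is
about 1.68 while the cancer-risk ratio is about 2.0), which is one reason
the published outputs are validated distributionally rather than
re-derived from inputs.

With `stochastic = TRUE`, the Monte-Carlo-relevant factors become
distributions: IR lognormal (CV 0.15, truncated to [0.2, 3]×mean), EF
uniform on [180, 365] days/year, ED lognormal (CV 0.10, truncated to
[1, 70] years), BW normal (CV 0.12, truncated to [0.4, 2]×mean). These CVs
were chosen once so that, with concentration variability dominating (as in
any field dataset), the rank order of influence is concentration > EF > IR
> ED with body weight negative — the qualitative ordering reported for the
study area. They are study conditions, not tuning knobs.

## Monte Carlo engine

`simulate_risk()` draws all stochastic inputs jointly (fixed draw order, one
seed) and pushes them through the dose equations, so a seed fully determines
the output. Reporting uses sorted-sample linear-interpolation quantiles
("type 7", the spreadsheet default, matching the study's toolchain) and
strict-inequality exceedance fractions (ties have probability zero under
continuous inputs). The default iteration count is 10 000 as in the study;
validation runs use $10^5$–$2\times10^5$ to shrink the Monte Carlo error
well below the comparison tolerances. `analytic_exceedance_normal()` is the
closed-form oracle the stochastic exceedance is checked against; the test
suite verifies the $1/\sqrt{n}$ convergence rate on a log–log slope.

Because the study publishes only output summaries (mean, SD, upper
percentiles, 5th/95th pairs) and not raw inputs, the published tables are
treated as *output-distribution* constraints: each row is, to within print
precision, normal at its (mean, SD) — verified row by row via
$\mathrm{mean} + z \cdot \mathrm{SD}$ against the printed percentiles —
except the right-skewed child Ni cancer risk, which a lognormal through its
(p5, p95) pair reproduces, including its published mean and its 1.12 %
exceedance of the $10^{-4}$ limit. The acceptance layer simulates from
those fitted distributions through the package's own draw/percentile/
exceedance machinery and compares against the published values.

## Distribution toolbox

`dist_spec()` covers point, normal, lognormal, uniform and triangular
families with optional truncation. Truncated sampling is inverse-CDF on the
standard-normal $z$ scale, switching to survival-function parametrisation
when the truncation window lies deep in the right tail (where `pnorm()`
rounds to 1 in double precision) — without this, strata whose fitted
`meanlog` sits far below the lower bound would produce infinite draws.
Draws are clamped to the bounds after the inverse transform, so the bounds
contract is exact, never approximate.

`fit_truncated_lognormal()` is the generator's moment matcher. Given a
target mean and SD inside bounds $[a, b]$, it solves the truncated-mean
equation exactly for `meanlog` at each candidate `sdlog` (1-D root solve,
using tail-stable closed-form truncated moments) and picks the `sdlog`
minimising the SD mismatch. Matching the mean exactly — rather than least
squares on both moments — is deliberate: some published strata put the
district mean almost on the range minimum (Iju Pb: mean 13 µg/L in
[11.7, 427.2]), where no truncated lognormal attains the implied SD at all.
The fit then keeps the mean honest and reports the best achievable SD in
the `"achieved_sd"` attribute, and downstream parameter-recovery statements
stay well-posed for every stratum.

## The synthetic generator

`generate_district_dataset()` draws one value per location from the
mean-exact truncated lognormal of its stratum and adds multiplicative
replicate noise at 5 % CV (emulating triplicate laboratory measurement),
clipping to the stratum bounds. Each (district, source, parameter) stratum
uses an independent substream seed derived by hashing the stratum key with
the master seed (all seeds kept below $2^{31}$), so datasets are
deterministic and strata independent. Detection status follows the study
design: Cu and Cd never detected; Cr measured in Iju wells only, below a
0.01 µg/L detection limit in Iju boreholes, absent at Atan.

Stratum targets come from the study's published per-district ranges and
means; stratum SDs are back-calculated from the coefficients of variation
of the published per-stratum hazard-quotient summaries (HQ is linear in
concentration, so the CVs transfer). Where the study publishes no SD (Ca,
Mg) a CV of 0.15 was chosen once as typical for major-ion chemistry; the EC
ranges, which the study omits, span roughly ±3 SD around its published
means. The published per-source dose tables and the per-district
concentration summaries are not perfectly consistent with one another (the
well-water Pb doses imply concentrations above the published district mean);
the generator follows the concentration summaries, which is why
pipeline outputs on synthetic data are structural, not numerical,
reproductions of the dose tables.

What the generator deliberately does **not** emulate: spatial
autocorrelation (the IDW module is exercised on explicit point sets),
inter-parameter correlation within a stratum (each parameter has an
independent substream; the factor-analysis recovery tests use the separate
`two_source_mixture()` generator with planted loadings), seasonal or
temporal structure, and instrument-level QA/QC. Passing tests therefore
demonstrate correctness of the statistical machinery under the design's
marginal structure, not field realism of any single simulated dataset.

Parameter recovery scales as $CV/\sqrt{n_{loc}}$: at the design size (9
locations) stratum means land within 25 % of target; at 900 locations the
moderate-CV strata (CV ≤ 0.35) recover their targets within 3 %, which the
acceptance suite checks across both districts. For the high-CV Pb strata
(CV up to 1.2) a 3 % bound at 900 locations would be below one Monte Carlo
standard error and is not a meaningful contract for any unbiased generator;
those strata are instead covered by the exact bounds and determinism
properties.

## Descriptive layer and censoring

Below-detection values enter descriptive statistics at half their detection
limit (the standard substitution convention); fully non-detected or
below-detection strata are excluded from risk simulation and listed as "not
screened" in the run manifest — mirroring how the study handled Cr in Iju
boreholes. Violation percentages are exact location-level ratios: replicates
are averaged to one value per location first (the published 44.44 % = 4/9
borehole arithmetic only works at location level), and the package reports
exact ratios (1/9 = 11.11 %, not the study's unexplained 11.13 %).
Standard deviations use the sample (n−1) convention of the spreadsheet
tools the study used. Correlation strengths are classed on $|r|$: weak
below 0.5, moderate to 0.6999, strong at or above 0.7, with the sign
reported alongside.

## Source apportionment

"Principal factor analysis" is implemented as principal-component
extraction on the Pearson correlation matrix, unrotated — the choice that
reproduces every reported quantity type (eigenvalue scree, explained and
cumulative variance, loadings, per-factor variable and observation
contributions) without guessing an unstated rotation. Columns are z-scored
before scoring, which the correlation-matrix decomposition implies; factor
signs are fixed so each factor's largest-magnitude loading is positive,
making loadings platform-reproducible. Retention supports a fixed count,
the Kaiser rule (eigenvalue > 1) and a cumulative-variance threshold.
Variable contributions are $100\,\ell_{vf}^2/\lambda_f$ and observation
contributions $100\,s_{if}^2/\sum_i s_{if}^2$, each summing to 100 per
factor. On the planted two-source mixture (18 observations × 10 variables,
communality 0.85) two retained factors explain well above 70 % of the
variance, the regime of the published 78.7 %/86.8 % figures.

## Sensitivity analysis

`contribution_analysis()` reports signed shares
$100 \cdot \mathrm{sign}(\rho_j)\,\rho_j^2 / \sum_k \rho_k^2$ from the
Spearman rank correlation of each input with the output. Squared-correlation
normalisation is the default because it approximates a variance share for
monotone models; since the study never names its algorithm, linear shares
($|\rho|$-normalised) are available via an argument. Spearman invariance
under monotone transforms, permutation equivariance, sign preservation
under added noise, and the constant-input → 0 % (with warning) contract are
all property-tested.

## Spatial interpolation

`idw_interpolate()` evaluates the inverse-distance-weighted interpolant
(power 2 by default, all points, planar Euclidean distance — the common GIS
defaults; the study names IDW but no parameters) at the cell centres of an
ESRI-ASCII-convention grid, with exact value assignment within
$10^{-9} \times$ cellsize of a data point. The interpolant is a convex
combination (never leaves the input range), depends on distances only, and
converges to nearest-neighbour as the power grows — each a tested property.
Grids round-trip through the plain-text `.asc` format bit-stably.
Coordinates are treated as planar; no geodesic correction or CRS handling,
appropriate for a study extent of a few kilometres.

## Pipeline and reproducibility

`run_full_assessment()` composes the stages (describe → simulate →
sensitivity → apportion → map) behind one validated configuration; each
stage emits deterministic CSV/`.asc` outputs, and `manifest.json` records
the package version, configuration hash, seeds, sample counts and every
metal skipped as not screened. A fixed configuration yields a byte-identical
bundle, and disabling one stage changes no byte of another's outputs — both
asserted in the test suite. A thin command-line wrapper over these functions
ships in `inst/scripts/aquarisk.R`; the exported functions are the primary
interface.

## Problem sizes

The test and validation runs use $10^4$–$2\times10^5$ Monte Carlo
iterations, 120-replicate convergence sweeps at $n = 10^3$–$10^5$, and
900-location generator runs — sizes chosen so that Monte Carlo error sits
comfortably below each comparison tolerance while the full suite stays
quick on a single CPU.

## Known limitations

- No mixture interaction: hazard quotients are per metal; any hazard-index
  summation is a reporting convenience, not a toxicological model.
- No toxicokinetics and no gastrointestinal absorption adjustment beyond
  the dermal-RfD override.
- The generator's independence across parameters means synthetic
  correlation matrices are null up to sampling noise; structure-recovery
  claims rest on the planted-loading generator.
- No kriging or variography; IDW is deterministic interpolation, and maps
  on synthetic coordinates are illustrative only.
- Published-output validation constrains output distributions, not the
  (unpublished) input distributions; agreement there shows the engine and
  reporting are right, not that the exposure defaults equal the study's.
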