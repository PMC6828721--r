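# aquarisk

Probabilistic human-health risk assessment of potentially toxic heavy
metals (Pb, Cr, Ni, Fe, Mn, Al) in groundwater, for environmental
scientists and public-health analysts working with well/borehole monitoring
data. The package implements the US EPA exposure chain

- chronic daily intake, ingestion and dermal:
  `CDI_ing = C·IR_w·EF_r·ED / (BW·AT_r)`,
  `CDI_derm = C·SA·K_p·EF_r·ED·ET·CF / (BW·AT_r)` (µg/kg·day),
- hazard quotient `HQ = CDI / RfD` (potential non-carcinogenic risk when
  HQ > 1),
- lifetime cancer risk `LTCR = CDI_ing × SF` against the 10⁻⁶–10⁻⁴
  acceptability band,

and propagates concentration and exposure-factor uncertainty through these
equations by seeded Monte Carlo simulation, reporting means, SDs, upper
percentiles (90/95/99/99.9) and exceedance fractions. Around that core it
provides guideline-violation accounting (WHO/NSDWQ), Spearman-based signed
sensitivity shares, correlation + principal-factor source apportionment
(eigenvalues, loadings, variable/observation contributions), and
inverse-distance-weighted interpolation onto ESRI ASCII grids.

Because studies of this kind typically publish summary statistics rather
than raw samples, the package includes a first-class synthetic generator
that reproduces a two-district (Atan, Iju), two-source (borehole, hand-dug
well) design — 108 samples from 36 locations in triplicate — from published
ranges, means and back-calculated SDs, via mean-exact truncated-lognormal
moment fits. Every pipeline stage runs end-to-end on generated data.

## Worked example

Simulate the adult nickel cancer risk for Iju boreholes from a generated
study dataset:

```r
library(aquarisk)

samples <- generate_study_dataset(seed = 1)      # 108 samples, 36 locations
st <- summarize_stratum(samples, "Ni", district = "Iju",
                        source_type = "borehole")
# $n 27, $min 5.99, $max 13.8, $mean 10.4, $sd 2.17   (µg/L)

conc  <- fit_truncated_lognormal(st$mean, st$sd,
                                 lower = 0.5 * st$min, upper = 2 * st$max)
adult <- default_exposure_profiles(stochastic = TRUE)$adult
rd    <- simulate_risk(conc, adult, metal = "Ni",
                       endpoint = "LTCR", n = 10000, seed = 42)

percentile_summary(rd)$mean          # 0.000164
percentile_summary(rd)$percentiles
#       p5      p50      p90      p95      p99    p99.9
# 8.39e-05 1.54e-04 2.43e-04 2.76e-04 3.52e-04 4.61e-04
exceedance_fraction(rd, 1e-4)        # 87.71
```

The mean simulated lifetime cancer risk (1.64 × 10⁻⁴) sits above the
10⁻⁴ acceptability limit and 87.7 % of simulated risks exceed it — nickel
is the carcinogenic driver in this district, as the hazard screening also
suggests. The signed sensitivity shares attribute the output spread to the
stochastic inputs (body weight negative, as it divides the dose):

```r
sensitivity_report(rd)
#  variable    rho contribution_pct
#      EF_r  0.559             33.3
#         C  0.544             31.5
#      IR_w  0.396             16.8
#        BW -0.324            -11.2
#        ED  0.260              7.2
```

`run_full_assessment(run_config(...))` chains all stages (descriptives →
risk tables → sensitivity → apportionment → IDW maps) into a deterministic
output bundle with a JSON manifest; `inst/scripts/aquarisk.R` is a thin
command-line wrapper over the same functions.

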