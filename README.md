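# glacierseg

Foraging-range segregation of colonial seabirds at tidewater glacier
fronts.

Breeding black-legged kittiwakes (*Rissa tridactyla*) are central-place
foragers: every foraging trip starts and ends at the colony. In Arctic
fjords, marine-terminating glacier fronts concentrate prey at the surface
through subglacial meltwater plumes, creating fixed, predictable foraging
patches. `glacierseg` is a complete, tested analysis chain for movement
and spatial ecologists asking whether such patches structure seabird
movements and drive fine-scale spatial segregation among neighbouring
colonies — and for anyone who wants the underlying machinery (trip
segmentation, autocorrelation-aware kernel UDs, utilization-distribution
overlap, permutation tests, mixed models, matrix regression) as reusable
functions.

## What it computes

From a table of GPS fixes, colony metadata and glacier-front geometries:

1. **Trips** — fixes subsampled to 10 min, speed-filtered at 80 km h⁻¹,
   segmented by a 200-m colony radius and a 50-min minimum duration, with
   mostly-over-land excursions removed.
2. **Utilization distributions** — per individual, an IID /
   Ornstein–Uhlenbeck (OU) / OU-Foraging (OUF) continuous-time position
   model is fitted by exact maximum likelihood and selected by AICc; the
   UD is a Gaussian-kernel density on a 500-m grid with reference
   bandwidth `H = σ̂² · N̂ₐᵣₑₐ^(−1/3)` evaluated at the *effective* sample
   size `N̂ₐᵣₑₐ` (duration / τ_pos ≈ number of range crossings;
   individuals below 4.5 are excluded).
3. **Segregation** — pairwise Bhattacharyya overlap `BA = Σ √(p·q)` on a
   shared lattice; segregation index `SI = 1 − BA`; global and pairwise
   ANOSIM (`R = (r̄_between − r̄_within)/(n(n−1)/4)`) with
   Benjamini–Hochberg correction and a multivariate-dispersion
   homogeneity check.
4. **Glacier-front use** — a front is used when two consecutive 10-min
   fixes fall inside its 400-m buffer; a binomial GLMM
   (`use ~ distance + sex + colony + (1 | individual)`, logit link) tests
   the distance decay, with likelihood-ratio tests, Nakagawa conditional
   R², and a simulation-based dispersion check.
5. **Drivers of segregation** — Bolnick front-use dissimilarity
   `DH = 1 − Σₖ min(p_ik, p_jk)`, and an MRM of the SI matrix on
   colony-size difference (Manhattan), colony separation (Euclidean) and
   DH, with significance from 999 row/column permutations.

A synthetic seascape + track generator (`sim_config()`,
`simulate_seascape()`, `simulate_tracks()`) emulates the study system —
five Kongsfjorden colonies, 25 glacier fronts within 50 km, 1–10 trips per
bird at 10-min fixes, and a multinomial-logit front choice with distance
slope −0.22 per km — so every stage can be checked against known ground
truth.

## Worked example

```r
library(glacierseg)

cfg <- sim_config(seed = 1)               # default study conditions
res <- run_pipeline(cfg, n_perm = 999, seed = 2)

res$anosim_global
#> <ANOSIM: R = 0.466, p = 0.001 (999 permutations)>

round(res$glmm$distance_slope, 3); round(res$glmm$distance_ci, 3)
#> [1] -0.235
#> [1] -0.274 -0.197

res$mrm
#> <MRM: R^2 = 0.575, F = 385.85, p = 0.001 (999 permutations)>
#>        term     estimate     p
#>   intercept 2.681952e-01 1.000
#>        size 1.791355e-05 0.171
#>  separation 9.746457e-06 0.001
#>          dh 1.119300e-01 0.114
```

Reading the output: of the 50 simulated birds, 45 passed the
effective-sample-size filter (206 complete trips). Space use is strongly
colony-structured — between-colony dissimilarity outranks within-colony
dissimilarity (ANOSIM `R` = 0.466 at the permutation floor p = 0.001).
Front use decays with colony–front distance on the logit scale at −0.235
per km, and the 95% CI covers the generating slope of −0.22 (the
likelihood-ratio test is decisive, χ²₁ = 460.5). In the MRM, colony
separation and (with this seed, weakly) front-use dissimilarity carry the
segregation signal while colony size does not — the generator gives
colony size no causal role.

A shell entry point with the same defaults is provided at
`inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R --seed 1 --out-dir pipeline-output
```

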