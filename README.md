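# morphorep

**How reliable is a fish morphometric method?** Population studies in
ichthyology use four common data types — "traditional" caliper distances
(TRA), truss-network distances from images (TRU), and geometric
morphometrics of body (GMB) or scale (GMS) landmarks. All four can
separate populations; they differ sharply in how well they agree with
themselves. `morphorep` is an R package for quantifying, on a fully
crossed species × site × individual × measurer × repeat design:

* **repeatability** — intra-measurer agreement of repeated datasets,
* **reproducibility** — inter-measurer agreement,
* **separative power** — statistical isolation of the source populations,
* **subjectivity** — the measurer's share of the variation.

It is aimed at morphometricians planning or auditing measurement
protocols, and at methodologists who need a tested reference
implementation of this comparison framework.

## The statistical core

*Size removal.* Landmark configurations go through generalized Procrustes
analysis (GPA): centring, scaling to unit centroid size CS, iterative
orthogonal least-squares rotation to the consensus, tangent projection,
then multivariate regression of shape on log CS; analyses use the
residuals. Linear distances are adjusted by the Elliott allometric
formula

&nbsp;&nbsp;&nbsp;&nbsp;M<sub>adj</sub> = M · (L<sub>s</sub> / L<sub>0</sub>)<sup>b</sup>

with L<sub>0</sub> the specimen's standard length, L<sub>s</sub> the mean
SL of the analysis set, and b the per-variable slope of log M on log SL;
a decorrelation recheck against SL confirms the adjustment.

*Concordance.* Every measurer-repeat dataset of a population becomes a
Euclidean distance matrix over its individuals; matched datasets are
compared with one-sided Mantel permutation tests (statistic R, p =
(1 + exceedances)/(1 + permutations), exhaustive for ≤ 8 individuals).
The R values are grouped by measurer, species and method and compared
with Kruskal–Wallis tests plus a compact letter display. The default
design yields 81 repeatability and 243 reproducibility comparisons per
method (324 and 972 over four methods).

*Separation.* On one random repeat per individual and measurer: canonical
variate analysis (generalized eigenproblem of between- vs pooled
within-group covariance after principal-component reduction) with
permutation-tested pairwise population detachment, and two-way crossed
PERMANOVA on Euclidean distances (pseudo-F per source, unrestricted row
permutation, df = (2, 2, 4, 261, 269) for a 3 × 3 × 30-per-cell species
analysis).

A seeded synthetic-data generator emulates the whole design — population
shape shifts, individual variation, per-measurer bias with a
per-individual interpretation component, per-record digitization noise,
allometric SL scaling — so the entire pipeline is testable without
specimens.

## Worked example

Simulate one species measured three times by three measurers at three
sites, remove size, and score repeatability:

```r
library(morphorep)

d   <- design_spec(n_species = 1, n_individuals = 12, seed = 42)
gmb <- generate_landmarks(d, effect_spec(), template = "body")
res <- regress_out_size(procrustes_fit(gmb))

concordance(res, "repeatability", n_perm = 199, seed = 42, method = "GMB")
#> Concordance table (repeatability): 27 pairwise Mantel tests
#>   R: mean 0.748, SD 0.098; significant at 0.05: 27/27
```

27 comparisons because each of 3 measurers contributes `choose(3, 2)`
repeat pairs at each of 3 sites; the mean Mantel R of 0.748 says a
measurer's repeated body-landmark datasets rank the same individuals as
mutually similar to a high degree, and every comparison is individually
significant.

Subjectivity and separative power on one random repeat per individual:

```r
am <- select_random_repeat(res, seed = 42)
permanova(am, n_perm = 999, seed = 42)
#> PERMANOVA on Euclidean distances (999 permutations)
#>       Source Sum of sqrs  df Mean square     F     p
#>         site   0.0527920   2    0.026400 18.15 0.001
#>     measurer   0.0138410   2    0.006920  4.76 0.001
#>  interaction   0.0011801   4    0.000295  0.20 1.000
#>     residual   0.1439900  99    0.001450
#>        total   0.2118000 107
```

Both site and measurer are significant, but F(site) = 18.15 far exceeds
F(measurer) = 4.76: for body landmarks, biology dominates the measurer
effect. (Caliper-style data generated with the default inflation factors
invert this contrast.) A per-measurer CVA classifies population
detachment:

```r
cva(am_m1, grouping = "site", n_perm = 999, seed = 42)
#> Canonical variate analysis: 3 groups, 2 axes
#>   % variance per axis: 69.7, 30.3
#>   detachment (alpha = 0.05): all-three (3 significant pair(s))
```

`run_pipeline(pipeline_config(...))` drives the full comparison (all four
methods, both concordance modes, level summaries with letters, CVA and
PERMANOVA per species) and writes a CSV report bundle plus a YAML
manifest; `inst/scripts/morphorep` exposes `synth`, `standardize`,
`concordance`, `separation` and `run` subcommands for shell use, reading
TPS or CSV input.

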