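---
title: "Comparing the reliability of fish morphometric methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the reliability of fish morphometric methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

Morphometric surveys of fish populations rest on four common data types:
caliper distances taken on the fish itself (TRA), truss-network distances
between homologous landmarks measured on an image (TRU), and landmark
coordinates digitized on body (GMB) or scale (GMS) images.  Any of these
can separate populations — but a measurement programme is only as good as
its agreement with itself.  `morphorep` quantifies four reliability
aspects of such methods when the same specimens are measured repeatedly by
several measurers:

* **repeatability** — agreement among one measurer's repeated datasets;
* **reproducibility** — agreement among different measurers' datasets;
* **separative power** — ability to distinguish the source populations;
* **subjectivity** — how much of the variation follows the measurer rather
  than the biology.

This vignette explains the statistical machinery, the choices behind its
defaults, and what the synthetic data generator does and does not emulate.

```{r setup}
library(morphorep)
```

## The measurement design

Everything operates on a fully crossed design: species × sampling site ×
individual × measurer × repeat.  The default `design_spec()` is 3 species
× 3 sites × 30 individuals × 3 measurers × 3 repeats — 2430 records per
method, i.e. 26,730 stored values for an 11-landmark body configuration,
17,010 for a 7-landmark scale configuration, and 38,880 for 16 linear
distances:

```{r}
d <- design_spec()
d
c(body = n_records(d) * d$n_landmarks_body,
  scale = n_records(d) * d$n_landmarks_scale,
  distances = n_records(d) * d$n_distance_vars)
```

## Removing size

Reliability must be judged on *shape*, not on how large the fish were.

**Landmark methods.**  `procrustes_fit()` performs generalized Procrustes
superimposition: every configuration is centred, scaled to unit centroid
size, and iteratively rotated onto the consensus (orthogonal least
squares, reflections disallowed since all specimens are photographed from
the left side) until the consensus changes by less than `tol` (default
1e-8 Frobenius norm, at most 100 sweeps).  The aligned shapes are then
projected orthogonally onto the tangent plane at the consensus so that the
subsequent linear statistics are valid; the consensus is rotated onto its
principal axes so results do not depend on the arbitrary orientation of
the input images.  Residual allometry is removed by `regress_out_size()`:
ordinary least squares of every tangent coordinate on the log of centroid
size, by default pooled per species (the analyses downstream run per
species, so one allometric trend per species is the natural granularity;
the pooling is configurable).  The residuals of this regression are the
size-free shape variables.

**Distance methods.**  `fit_allometry()` estimates, per variable, the
power-law exponent *b* of measurement against standard length (SL) as the
common within-group slope of log10 M on log10 SL (groups default to
site within species, slopes pooled weighted by group degrees of freedom),
and `standardize()` adjusts every measurement to the overall mean length
Ls:

M_adj = M · (Ls / L0)^b.

This is the classical ratio-form allometric adjustment.  A subtraction
variant of the formula circulates in print; it is dimensionally
inconsistent, not idempotent, and undefined for fish longer than Ls under
a fractional exponent, so it is implemented only behind
`form = "printed"` for forensic comparison.  `recheck_decorrelation()`
verifies the outcome: after adjustment no variable should correlate with
SL.

```{r}
dd <- design_spec(n_species = 1, n_individuals = 10, seed = 7)
tru <- generate_distances(dd, effect_spec(), mode = "truss")
mod <- fit_allometry(tru)
mod
adj <- standardize(tru, mod)
summary(recheck_decorrelation(adj)$pass)
```

Note that with many records (each individual appears measurer × repeat
times) the decorrelation test has enormous power, so tiny residual
correlations left by estimation error in *b* can reach significance in
large designs; the check is a diagnostic, not a gate.

## Scoring agreement: Mantel concordance

One "dataset" is one measurer's repeat for one population.  Each dataset
is converted to a Euclidean distance matrix over its individuals, and two
matched datasets are compared with a one-sided Mantel test
(`mantel_test()`): the statistic R is the Pearson correlation of the
lower-triangle entries, significance comes from jointly permuting the rows
and columns of one matrix, with p = (1 + exceedances) / (1 + permutations).
For 8 or fewer individuals all permutations are enumerated instead.  R is
reported as computed — it can be negative and is never clamped.

`concordance()` runs every pair the design admits:

* repeatability: all `choose(repeats, 2)` repeat pairs per (species, site,
  measurer) — 81 per method for the default design;
* reproducibility: all `choose(measurers, 2)` measurer pairs × repeats²
  dataset pairings per (species, site) — 243 per method.  Every repeat of
  one measurer is compared against every repeat of the other, which is
  what the per-population comparison counts force.

The R values are then grouped hierarchically — by measurer within species,
by species within method, and by method — and compared with Kruskal-Wallis
tests (`group_and_compare()`): an omnibus H per family, pairwise two-group
tests at α = 0.05, and a compact letter display built by an insert-absorb
pass over the non-significance graph.  Pairwise tests are uncorrected by
default, matching the conventional reporting of such comparisons; Holm or
Bonferroni correction is available via `p_adjust`.

```{r}
res <- regress_out_size(procrustes_fit(generate_landmarks(dd, effect_spec())))
ct <- concordance(res, "repeatability", n_perm = 199, seed = 1, method = "GMB")
ct
```

The number of Mantel permutations is configurable (default 999 here;
permutation count affects only p resolution, not R, and R is what the
level comparisons use).

## Separative power and subjectivity

Separation analyses use one randomly chosen repeat per individual and
measurer (`select_random_repeat()`, seeded), giving 270 specimens per
species under the default design.

`cva()` is a canonical variate analysis: after projecting onto principal
components with non-negligible variance (shape residuals are rank
deficient by construction — dimension 2K − 4 at most — and small designs
can have more variables than specimens), the axes solve the generalized
eigenproblem of between-group against pooled within-group covariance.  At
most groups − 1 axes are kept; per-axis percentages of among-group
variance sum to 100; axis signs are fixed by making the largest loading
positive so plots reproduce.  Pairwise population separation
("detachment") is tested with two-group one-way PERMANOVA on the Euclidean
distance matrix at α = 0.05, uncorrected, and for three populations the
number of significant pairs maps to the classes none / one / two-of-three
/ all-three.  Whether a software package would test detachment by
MANOVA statistics instead is a genuine alternative; the permutation route
is used here because it matches the distance-based framework of the rest
of the pipeline, and it is documented as this package's choice.

`permanova()` partitions the sum of squared inter-point Euclidean
distances over a crossed, balanced site × measurer design via the doubly
centred Gower matrix: main effects and interaction each get a pseudo-F
against the residual mean square, and p-values come from unrestricted
permutation of specimen rows with every pseudo-F recomputed (9999
permutations by default; restricted permutation schemes are deliberately
out of scope).  The partition satisfies SS_site + SS_measurer +
SS_interaction + SS_residual = SS_total to numerical precision, degrees of
freedom are (a−1, b−1, (a−1)(b−1), n−ab, n−1) — (2, 2, 4, 261, 269) for
the default species analysis — and for Euclidean distances on a univariate
one-way layout the pseudo-F equals the classical ANOVA F exactly.

## The synthetic generator

`generate_landmarks()` and `generate_distances()` simulate the full
crossed design so every downstream stage is testable without specimens.
Landmark data: each species has a template configuration (a stylized
lateral fish outline, or a cycloid-scale polygon with an optional
high-curvature "characteristic" variant); populations displace the
template along orthonormal directions in shape space; individuals add
isotropic Gaussian shape variation; the individual's standard length
(log-uniform in `sl_range`) scales the configuration, and an
individual-specific rotation/translation places it in the image — one
photograph per fish, digitized by everyone.  Distance data: each variable
is a base proportion of body size scaling as SL^b with log-normal
population, individual, measurer and repeat effects.

The measurer effect has two parts, both proportional to the
`measurer_bias` / `measurer_cv` knob: a systematic offset drawn once per
measurer (which reproduces the "ghosting" of group centroids in
ordinations and drives the measurer pseudo-F, but cancels inside
within-dataset distance matrices — the Mantel statistic is insensitive to
a constant shift), and a measurer-by-individual interpretation component,
fixed across a measurer's repeats, which is what actually separates
reproducibility from repeatability.  For caliper data the interpretation
component is damped by the noise inflation factor: there is no image to
re-read, the specimen is re-handled every time, so caliper error is
per-record — which is why caliper repeatability and reproducibility come
out equally poor rather than diverging.

Default magnitudes: the study the generator emulates reports no
quantitative error model, so the defaults were fixed once at
field-realistic values implementing the intended error ordering
caliper ≫ truss ≈ scale landmarks ≫ body landmarks: shape-unit SDs of
0.035 (population shift), 0.01 (individual), 0.004 (measurer bias and
digitization noise for body landmarks), scale-landmark inflations ×1.4
(noise) and ×3 (bias), distance CVs of 0.02/0.05/0.02/0.035
(population/individual/measurer/repeat), caliper inflations ×2 (noise)
and ×6 (bias), allometric exponent 1.1, SL 60–135 mm.  The population
shift is deliberately larger than the total body-landmark measurer offset
and the caliper measurer bias is deliberately larger than the caliper
population signal, because site-dominated landmark ordinations and
measurer-dominated caliper ordinations are the phenomena the generator
exists to emulate.

What the generator does *not* emulate: non-Gaussian digitization blunders
(mis-ordered landmarks, data-entry errors), specimen degradation between
measurement rounds, correlated landmark placement errors along outlines,
size-dependent measurement error, and unbalanced or incomplete designs.
Passing tests on synthetic data therefore demonstrate that the statistical
machinery recovers known structure under the stated error model — not that
real measurement error has this structure.

```{r, fig.width = 6, fig.height = 4}
cfg <- pipeline_config(methods = c("GMB", "TRA"),
                       design = design_spec(n_species = 1,
                                            n_individuals = 10, seed = 3),
                       n_perm_mantel = 99, n_perm_permanova = 199,
                       seed = 3, verbose = FALSE)
rep <- run_pipeline(cfg)
rep
rep$results$TRA$sp1$permanova
```

## Numerical choices and edge cases

* Procrustes convergence: 1e-8 on the consensus change, 100 sweeps,
  error (not silent acceptance) on non-convergence; coincident-landmark
  specimens are named in the error.
* Constant log centroid size within a regression group gives a zero slope
  with a warning (error under `strict = TRUE`).
* Zero measurements are excluded from allometric slope fits (log
  undefined) with a warning; zero-variance variables report `NA` in the
  decorrelation check rather than a spurious correlation.
* Mantel tests refuse zero-variance distance matrices rather than
  returning `NaN`; exhaustive enumeration is capped at 8 individuals.
* Kruskal-Wallis uses midranks with the standard tie correction via
  `stats::kruskal.test`; groups in practice hold 9+ values, where the
  chi-square approximation is adequate.
* All stochastic stages draw their seed from one master seed via named
  sub-streams (`stage_seed()`), so adding a stage never shifts another
  stage's stream and a configuration plus seed reproduces every file
  byte-for-byte.

## Problem sizes used in the test-suite simulations

The calibration and recovery simulations in the package's tests run at
reduced sizes chosen to keep the checks sharp but quick: null calibration
of the Mantel and PERMANOVA tests uses 1000 replicates at 10–18 specimens
with 99 permutations each (the rejection rate at α = 0.05 must fall in
[0.035, 0.065]); the method-contrast recovery uses 20 generator seeds at
12 individuals per site; exponent recovery uses 10 replicates at n = 200.
These sizes are the package's own choice of a precision/runtime trade-off
and are documented here so they can be scaled up for a more stringent
run.

## Known limitations

* Semilandmarks, missing-landmark estimation, 3-D configurations and
  asymmetry decomposition are out of scope.
* Only Euclidean distance feeds the Mantel and PERMANOVA machinery
  (no Mahalanobis or Procrustes-distance alternatives), and partial
  Mantel tests are not provided.
* PERMANOVA requires a balanced crossed design, as in the study design it
  serves; dispersion (PERMDISP) testing is not included, so a significant
  factor can in principle reflect spread as well as location.
* The pairwise detachment classification is uncorrected for multiple
  testing by default (a correction option exists), mirroring conventional
  reporting rather than best inferential practice.
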