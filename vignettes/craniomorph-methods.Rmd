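---
title: "Methods: cranial shape analysis with craniomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cranial shape analysis with craniomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

`craniomorph` implements the analysis chain used in landmark-based studies
of cranial shape across mixed extant and fossil samples. This vignette is
the package's own account of the statistical procedures, the choices made
where the methodology was genuinely open, and what the synthetic-data
tests do and do not establish about real data.

## Data model

A dataset is a long tibble: one row per specimen × landmark, with columns
`specimen_id`, `taxon`, grouping metadata, `landmark` (1-based index into
a `landmark_scheme`), and coordinates `x`, `y`, `z` in digitiser units
(mm; units are carried opaquely — superimposition removes scale). A
landmark with any `NA` coordinate is absent and excluded from every
computation. The default `cranial_scheme()` has 33 landmarks: 3 midline
points and 15 bilateral pairs on sutures, the occipital condyles, and the
tooth row, placed so they survive on incomplete fossil crania. Internally
landmarks are 0-free 1-based indices end to end; files are read and
written with TPS (`LM3=` blocks, `NA` missing tokens), NTS (header-declared
sentinel `-999`), Morphologika (read-only), and a long CSV dialect (blank
fields for missing values; a `9999`-style magic triple is deliberately not
used because it cannot be distinguished from data).

## Mirror imputation

Fossil skulls usually preserve one side of a bilateral structure. For
each specimen the sagittal plane is fitted by total least squares to all
present midline landmarks plus the midpoints of bilateral pairs with both
members present: the plane passes through the centroid of those fitting
points and its normal is the smallest-eigenvalue eigenvector of their
scatter, oriented toward the side holding the majority of right-member
landmarks. A landmark missing on one side only is imputed as the
reflection of its antimere; pairs missing on both sides stay absent (with
a warning) rather than being guessed.

Open choices, decided as follows:

* **Per-specimen planes**, not a consensus plane: each specimen's own
  symmetry information is used, which is robust when only the three
  midline points and a few complete pairs survive. At least 3
  non-collinear fitting points are required; otherwise the fit aborts.
* **Single plane reflection**, not full Procrustes-based object-symmetry
  matching: reflection is the minimal model implied by one-line
  descriptions of mirroring in the literature, is an exact involution,
  and never alters present landmarks. Imputed landmarks are flagged in
  the output (`imputed` column, plus a per-landmark report) but treated
  identically downstream.

On exactly symmetric configurations any single-side deletion is recovered
to machine precision. Under per-coordinate Gaussian noise σ the imputed
point differs from the deleted original by ≈ √6·σ on average (two
independent noise draws in three coordinates) plus a plane-estimation
term; the test suite verifies the practical bound of 3σ.

## Generalized Procrustes analysis

Configurations are centred and scaled to unit centroid size, then
iteratively rotated to the running consensus; the consensus is the
arithmetic mean shape, re-centred and unit-scaled between sweeps purely as
an iteration device. Convergence is declared when the consensus moves by
less than `tol = 1e-10` (root summed squared change), with a 100-sweep cap
(5–10 sweeps suffice in practice; non-convergence returns a result with
`converged = FALSE` and a warning). Choices:

* **Unit-centroid-size scaling with rotation only** — every aligned shape
  has centroid size exactly 1, the convention of the major morphometric
  packages. Reflections are never admitted in the rotation fit: left and
  right are anatomically fixed.
* **Initialisation** by the first specimen. To make the result genuinely
  independent of that choice and of any rigid motion of the inputs, the
  converged solution is put in a *canonical orientation*: the consensus
  is rotated to its principal axes, with the sign of the first two axes
  fixed so the largest-magnitude coordinate along each is positive and
  the third axis completing a right-handed frame. With distinct
  consensus principal moments (the generic case for skull-like data) the
  output is then a deterministic function of the shapes alone; the test
  suite verifies invariance to random rigid motions and scalings at
  1e-8. Exactly degenerate principal moments (e.g. artificial data with
  perfect rotational symmetry) would make the orientation arbitrary,
  though still valid.
* **Tangent projection**: aligned shapes (unit vectors in configuration
  space) are projected orthogonally onto the hyperplane normal to the
  unit consensus vector, tᵢ = xᵢ − ⟨xᵢ, ĉ⟩ĉ, the standard linearisation
  in which Euclidean multivariate statistics approximate Procrustes
  geometry. The approximation is excellent at the within-order shape
  distances simulated here (≲ 0.2 Procrustes units).

`pool_by_species()` averages each species' aligned coordinates,
re-normalises, re-rotates to the consensus, and re-projects — the
"pooled by species" observation unit that reduces uneven specimen
sampling across taxa.

## Ordination and shape models

`shape_pca()` is covariance PCA (divisor n − 1) of tangent coordinates.
Correlation PCA is deliberately not offered: shape coordinates share
units, and rescaling them coordinate-wise would distort Procrustes
geometry. Component signs are made deterministic by forcing each loading
vector's largest-magnitude element positive (PC signs are otherwise
arbitrary and backend-dependent). Retained components are the non-null
dimensions (at most n − 1; superimposition itself removes 7 of the 3k raw
dimensions). `shape_model()` reconstructs the configuration mean + s·v
along any axis — the wireframe endpoints of ordination figures.

Whether ordinations should use specimens or species means is a genuine
ambiguity in pooled designs; both are supported (`pool_by_species()` is a
separate, explicit step) and neither is asserted as canonical.

## Allometric correction

`regress_shape_on_size()` fits every tangent coordinate on a size
covariate by OLS, pooled across groups (one common allometric slope —
per-group trajectories are out of scope). The residuals, which are exactly
uncorrelated with the covariate, feed `allometry_corrected_pca()`. The
default covariate is **raw centroid size**; log centroid size — the more
common modern convention — is a switch (`size_covariate = "log"`). Raw CS
is the default because the package's replication preset follows sources
that state "centroid size" without a transform; analyses of samples
spanning large size ranges should prefer the log switch. The reported
`percent_predicted` is 100 × (variance of fitted values)/(total variance).

## Discriminant analysis

Tangent data are rank-deficient (3k = 99 dimensions versus tens of
observations), so a pooled within-group covariance on raw coordinates is
singular. `pairwise_dfa()` therefore projects the two groups' pooled
observations onto their own principal components, retaining
d = min(nₐ + n_b − 3, rank) dimensions by default, and computes the
Mahalanobis distance D between group means under the pooled within-group
covariance in that subspace. The p-value is a group-label permutation test
(999 permutations by default, add-one estimator (1 + #{D* ≥ D})/(1 + B)).
Cross-validation is leave-one-out: group means and the pooled covariance
are refit without the held-out observation, which is assigned to the
nearer mean by Mahalanobis distance; exact ties go to the first group (and
are deterministic). The PC subspace itself is held fixed across folds —
refitting it per fold would change the coordinate system, not the
classifier, and makes fold results incomparable.

The default d is the largest subspace that keeps the pooled covariance
invertible, but at d ≈ n the covariance is ill-conditioned and both D and
LOO become unstable (distances inflate; single specimens flip
assignment). For the group-swap experiment, whose conclusion rests on
cross-validated reassignments, the package's own analyses use a
regularised subspace (`subspace_dim = 10`); the dimension is exposed
everywhere and reported in every result.

`group_swap_dfa()` formalises the contested-affinity design: a movable
group is merged into each of two host groups in turn. Merging it into its
true source distribution sharpens the between-host contrast (larger D,
no movable reassignments); merging it into the wrong host contaminates
that host's mean and covariance, and cross-validation reassigns movable
specimens back across the boundary.

## Disparity

Disparity is Procrustes variance: the trace of the tangent-coordinate
covariance (divisor n − 1; a single observation has disparity 0). The
n − 1 divisor is chosen for unbiasedness and is explicit rather than
hidden. Two resampling tests are provided, both seeded and both using the
add-one estimator:

* `disparity_difference_test()` — two-sided bootstrap of V_a − V_b,
  resampling observations with replacement from the pooled set into
  groups of the original sizes.
* `inclusion_test()` — the disparity change V(core ∪ added) − V(core)
  when fossil taxa are added to a group, with a one-sided (increase)
  permutation null in which core/added labels are shuffled on the union.
  One-sided because the scientific claim it addresses is directional.

Disparity is computed on specimen-level, *pre-allometry* tangent
coordinates; `run_pipeline()` enforces this ordering whenever allometric
correction is enabled.

## The synthetic generator

`simulate_skulls()` draws every specimen as

> template + group effect + species offset + (log s − mean log s) ·
> allometry vector + iid Gaussian noise,

in tangent space at a deterministic, exactly symmetric template skull
(midline on y = 0, unit centroid size), then rescales to the drawn
centroid size s (log-normal), applies a random rigid motion, and — for
fossil-style specimens — deletes right-side members of bilateral pairs
with the configured probability. Planted vectors are projected out of the
7 similarity directions (translations, scaling, infinitesimal rotations)
at the template, so superimposition cannot absorb any planted signal and
analytic expectations are exact. Everything is reproducible from one
seed.

Default magnitudes (per-coordinate, Procrustes units): noise σ = 0.01 —
the scale implied by a digitiser accurate to ~0.2 mm on ~100 mm crania
plus individual variation; log centroid size mean log(100), sd 0.2;
group effects 0.05 total magnitude. The study-mimic `primate_preset()`
uses six groups whose species counts (19/1/6/3/3/2) echo a real mixed
extant/fossil euprimate sampling, a clade axis of total magnitude 0.18
separating haplorhine-like from strepsirrhine-like groups, adapiform-like
specimens drawn from the strepsirrhine side, larger species-level spread
among anthropoid-like species (so haplorhine disparity exceeds
strepsirrhine, at the 0.01–0.03 total-variance scale reported for real
primate crania), fossil-lemur-like species displaced into novel
morphospace, size sd 0.6 log units with an allometric direction of 0.12
per log unit, and 40% right-side missingness on the two fossil groups.
These values were fixed once, from the scales the field reports, and are
not tuned per analysis.

What the generator does **not** emulate: phylogenetic covariance among
species (species offsets are iid), biomechanical constraint or
integration among landmarks (noise is isotropic), digitising error that
varies by landmark accessibility, taphonomic deformation, and
missingness mechanisms other than loss of one side. Passing tests
therefore demonstrate correctness of the algorithms and calibration of
the resampling tests under a clean, exchangeable model — not robustness
to correlated noise or non-random fossil damage.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest sizes
chosen as adequate for the properties they check: 50-specimen GPA
invariance sweeps, 100-replicate imputation error, 200-dataset null
calibrations with 199 resamples each, 50-replicate group-swap
experiments, and a 136-specimen (34-species) study-mimic pipeline run.
Key tolerances: GPA convergence 1e-10; invariance checks 1e-8; exact
linear-algebra identities 1e-9–1e-12; Monte-Carlo bounds verified by
pilot simulation before being frozen. Degenerate inputs (single
landmarks, zero-size configurations, collinear plane fits, constant size
covariates, empty groups, single-observation PCAs) raise errors that name
the failing precondition; rank-deficient DFA subspaces are reduced
automatically with a warning.

## Interface note

The package's analysis surface is R functions returning tibbles and
fitted objects (with `tidy()`/`glance()`/`augment()`/`autoplot()`
methods), plus `run_pipeline()` for the full seeded sequence and
`scripts/acceptance.R` as a command-line entry point for the end-to-end
reproduction run. A subcommand-style CLI would add nothing for the
package's R-native audience and is intentionally not provided.

## Known limitations

* Sliding semilandmarks, resistant-fit superimposition, and 2D data are
  unsupported.
* Thin-plate-spline or regression-based missing-landmark estimation is
  not offered; reflection is the only imputation.
* Multi-group canonical variates analysis is out of scope; discrimination
  is strictly pairwise (with the swap construction for three-group
  questions).
* Mahalanobis distances in near-saturated subspaces are reported as
  computed but should be interpreted with the subspace dimension in
  hand.
* The permutation and bootstrap nulls assume exchangeability of
  observations; phylogenetic non-independence among species violates
  this and is not modelled.
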