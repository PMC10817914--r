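---
title: "How white-matter connectome architecture constrains cortical-thickness maturation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome constraints on cortical maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Cortical thickness (CT) thins markedly between childhood and adolescence,
but not uniformly: some regions mature faster than others, and regions that
are wired together by white-matter (WM) tracts tend to mature together. This
package implements, end to end, an analysis of that coupling: it maps
per-parcel CT maturation from longitudinal scans, asks whether a parcel's
maturation is predicted by the mean maturation of its directly WM-connected
neighbors, models multi-step interactions with a random-walk diffusion
process on the binary connectome, predicts the maturation map from per-scale
diffusion profiles with cross-validated support-vector regression (SVR),
identifies "dominant" parcels whose diffusion profiles resemble the whole
maturation map, and contrasts gene-set expression between dominant and
non-dominant territory.

Because the source MRI and postmortem datasets are access-restricted, the
package is exercised entirely on synthetic data whose generators are
first-class, tested code. The generators emulate the statistical structure
the analysis assumes; they do not emulate images, tractography, or cortical
folding.

## Synthetic study conditions

`gen_parcellation()` places `n/2` parcels per hemisphere on a unit sphere
with a Fibonacci lattice (deterministic, even coverage) followed by a seeded
rotation about the left-right axis; left and right centroids are exact
mirror images. Spatial adjacency — the "shares a parcel boundary" relation
that the exclusion variant and the noise-smoothing pass need — is the
spherical Delaunay triangulation per hemisphere, computed by stereographic
projection (circle-preserving, so the planar triangulation is the spherical
one). System labels are a nearest-seed (Voronoi) partition; each system is
contained in one hemisphere so that every label is a connected patch under
the per-hemisphere adjacency (a bilateral system would be split by
construction). Laminar labels are four equal-frequency superior–inferior
bands.

`gen_connectome()` wires parcels with probability proportional to
`exp(-d/length_scale) * (1 + bonus * same_system)` and adds the Euclidean
minimum spanning tree so the result is connected. The defaults — density
0.08, `length_scale` 0.5 (a decay length about 15% of the brain's extent,
in line with the strong exponential distance dependence of inter-regional
connection probability), `within_system_bonus` 4 — give a within-system
edge fraction near 0.7 and a within-system first-scale diffusion mass near
0.7 that falls toward 0.3 at the diameter, the qualitative within-to-between
pattern the analysis expects of a real backbone. These defaults are the
package's study conditions and are used unchanged by the tests and the
acceptance script.

`gen_longitudinal_ct()` emulates an accelerated longitudinal design: a
configurable mix of single-, double- and triple-scan subjects (default
158/105/51, which yields 521 scans and 207 consecutive scan pairs),
first-scan ages uniform on 6–13 y, repeat scans 0.8–1.2 y apart, a per-scan
group label at the age-10 cut, per-node baselines near 2.5 mm, a sex
covariate, a subject random intercept (default sd 0.1 mm) and iid scan
noise (default sd 0.05 mm). With all noise terms zero the
adolescent-minus-child mean per node equals the planted effect exactly,
which the tests assert to 1e-10.

`gen_effect_map()` plants maturation effects as weighted sums of symmetrized
diffusion-profile rows of chosen dominant nodes plus spatially smoothed
noise (one adjacency-averaging pass over iid Gaussians — the minimal model
that gives maps positive spatial autocorrelation, which the spin test needs
to be a meaningful null). The spatial-autocorrelation strength of real
maturation maps is not known precisely, so the noise level is exposed as a
parameter rather than fixed; where the test suite needs a single "moderate
noise" condition it uses noise sd equal to half the sd of the noiseless
planted map.

`gen_gene_panel()` builds region-by-age expression samples in which genes of
a target set share a latent age trajectory whose level differs between
dominant and non-dominant regions by a configurable divergence, against iid
background genes.

## Maturation models

*Model I (group contrast).* Per node, thickness is regressed on group
(child vs adolescent, per scan), sex, and — when several sites are present —
site, with a per-subject random intercept and, when identifiable, a
per-subject random group slope (`lme4`/`lmerTest`, Satterthwaite t and p).
The random slope is unidentifiable for subjects observed in only one group,
so the fit falls back to the intercept-only structure on non-convergence or
a singular fit and records the fallback per node. When every subject has a
single scan, the random intercept is confounded with the residual and the
model is fit as ordinary least squares (vectorized across nodes), which
makes the degenerate case exact rather than approximate. The reported t is
the child-minus-adolescent contrast, so thinning is positive; the
significance mask is Bonferroni-corrected two-sided p at `alpha/n_nodes`
(5e-5 for 1000 nodes at alpha 0.05).

*Model II (age trajectories).* Per node, a thin-plate regression spline of
thickness on age with sex and a subject random intercept, smoothing
parameter by REML (`mgcv`). The basis dimension defaults to 5 — enough for
the monotone-to-curvilinear shapes expected at a few hundred scans without
inviting wiggle — and the maturation rate at an evaluation age is the
central finite difference of the fitted smooth with a 0.01-y step, small
against the ~8-y age range but large against numerical noise.

*Model III (individual rates).* Consecutive scan pairs (a k-scan subject
contributes k−1 pairs) give per-node annualized change
`(CT_second − CT_first) / Δage`; negative is thinning.

*System enrichment.* A system's mean map value is z-scored against the
per-system means of spin-surrogate maps; constant maps would make the null
sd zero, so that case returns z = 0 with a warning.

## Neighbor constraint and its nulls

The neighbor-mean estimate of node i is the mean map value over its graph
neighbors; degree-0 nodes are excluded and counted. The constraint
correlation is the Pearson r between map and estimate. Two confound
variants: `excluded` recomputes the estimate over graph neighbors that are
not spatial neighbors (dropping nodes left with none), and `regressed`
residualizes the estimate — not the observed map, which keeps the observed
quantity untouched — on each node's mean Euclidean distance to its
neighbors.

Two surrogate families assess significance. The spin test draws a uniform
random rotation (unit quaternion), applies it to left-hemisphere centroids
and its x-mirrored twin to the right hemisphere (standard practice for
bilateral maps), and assigns each original parcel the value of the nearest
rotated parcel within its hemisphere, duplicates permitted; this reassigns
the map while preserving its spatial autocorrelation, which the tests
verify via Moran's I. On coarse parcellations the duplicate-permitting
projection slightly inflates surrogate smoothness — a conservative bias —
whereas forcing a one-to-one matching (`unique_assignment = TRUE`) deflates
it and over-rejects; the conservative projection is therefore the default.
Calibration is assessed with maps from `gen_autocorrelated_map()`, an
isotropic Gaussian process on the sphere: isotropy makes such maps
exchangeable under rotations, which is the premise of a spin-test
calibration check. Maps built by smoothing noise over the parcel adjacency
are deliberately not used there — they are smooth with respect to the same
local scale the distance-dependent connectome wires, so they are not
network-independent and no rotation null can (or should) be calibrated
against them. The rewired null bins edges into equal-frequency
Euclidean-length bins and performs degree-preserving double-edge swaps
within bins, rejecting swaps that create self-loops or multi-edges or leave
the bin; every surrogate keeps the exact degree sequence and exact per-bin
counts. Empirical p-values use the (k+1)/(n+1) permutation convention — the
plain fraction, which can return p = 0, is available via
`plus_one = FALSE`. Surrogate connectivity is not enforced; operations that
need a connected graph redraw disconnected surrogates and say so.

The number of length bins is genuinely open configuration (10 by default).
It matters scientifically: with distance-dependent wiring and spatially
contiguous systems, a map planted from one or two diffusion-profile rows is
spatially smooth, and a 10-bin rewired null — which preserves geometry
almost exactly — reproduces its neighbor coupling, so the observed r sits
inside the null distribution no matter how strong the planted signal. That
null answers "is the coupling more than geometry plus degrees?", which a
geometrically planted map cannot answer affirmatively by construction. The
recovery checks in the test suite therefore run the rewired null unbinned
(`n_bins = 1`, plain Maslov–Sneppen rewiring), which answers the recovery
question actually being asked — "is the planted topological coupling
detected against degree-matched chance?" — while the calibration checks and
the empirical-style drivers keep the conservative 10-bin null.

## Diffusion model, prediction, dominance

The one-step transition matrix is `P = D^-1 A`; m-step propagation `P^m`
(identity start) is computed densely up to M = the graph diameter, exact
and cheap at study scale (≤ 1000 nodes), and symmetrized as
`S_m = (P^m + P^m') / 2` to represent bidirectional diffusion. Feature
vectors keep the diagonal (the return probability is part of the row
semantics); `drop_self` removes it for sensitivity checks.

SVR prediction treats nodes as samples and scale-m profile rows as
features: 10-fold cross-validation, linear kernel, cost chosen per outer
fold by inner 5-fold selection over the 16-value grid 2^-5..2^10 (nested
selection avoids the optimism of pooled selection). Features are z-scored
with training-fold statistics; the target is also standardized per training
fold so the epsilon-insensitive width (0.1) is in target-sd units — without
this, targets much smaller than epsilon produce an empty support-vector set
(that degenerate case is guarded and returns the training-mean prediction).
Accuracy is the Pearson r between observed values and assembled out-of-fold
predictions; feature contributions are the mean absolute linear weight per
feature across outer folds. Significance re-runs the identical CV on spun
targets (spin null) and on profiles of rewired networks (rewired null).

Dominance likelihood is the cosine similarity — raw vectors, since cosine
is what is meant, with `centered = TRUE` giving the correlation variant —
between each node's `S_m` row and the signed maturation map; per node and
scale, a one-sided spin p thresholds the dominant mask at 0.05, with no
across-scale multiplicity correction (the conjunction over scales is the
summary). The rank-based alternative averages the ascending ranks (mean
rank on ties) of the map and its neighbor-mean estimate. On planted data
the two likelihoods agree (Spearman r above 0.5 in the acceptance check),
the desk-scale analogue of the published cross-method agreement. With two
planted nodes the node-level maximum of the likelihood can legitimately
fall on a node between them — a mixture of two bumps resembles intermediate
profiles more than either generator — so single-node plants are the
identifiability check, and two-node plants are checked through the
significance mask's recall.

## Gene contrasts

Gene-set scores are projections onto the first principal axis of the
column-standardized set submatrix, fit jointly over all samples (the
per-category alternative would confound the contrast with rotation
differences); zero-variance genes are dropped with a warning and the sign
is fixed so the mean loading is nonnegative. The dominant-minus-non-dominant
difference in mean PC1 score, within an age window defaulting to 6–14 y
(the childhood-to-adolescence span of the imaging cohort; the window is
configurable), is tested against same-size gene sets resampled from the
remaining panel, categories held fixed, one-sided in the observed
direction. Map–gene correlation spins the phenotype (the likelihood map),
not each gene map, so one shared ensemble makes per-gene p-values
comparable; two-sided spin p-values get Benjamini–Hochberg correction
across genes, with the granularity floor 1/(n_spin+1) inherited from the
permutation p.

One caveat the tests make explicit: gene-resampling is a competitive null
and is calibrated only when the target set is exchangeable with the
resampling pool. A set whose genes share a latent trajectory has a
different contrast sampling distribution than resampled sets of independent
genes even when no category divergence is planted, so calibration is
checked on background-gene sets, and p-values for internally correlated
sets should be read as evidence against "no more divergence than a random
set", not as exact error rates.

## Problem sizes, reproducibility, limitations

The test suite and the acceptance script run the full analysis at 100 nodes
with 99-surrogate ensembles, calibration loops of 200 simulations, and
recovery loops of 20 seeds; the analysis drivers use 999 surrogates. Two
calibration details are deliberate: the spin-calibration loop draws a fresh
surrogate ensemble per simulation (with one shared ensemble the trials are
dependent and a binomial interval misdescribes the observed rate) and runs
at 300 nodes — within the study's own 219/448/1000 resolution range —
because the nearest-parcel projection is measurably conservative on a
50-parcel hemisphere (rejection 0.007 at nominal 0.05) and approaches
nominal as parcels shrink relative to the map's correlation length. All
generators and surrogate families are pure functions of their parameters
and a seed, the pipeline refuses configurations with a missing stage seed
before any computation, and two runs of the same configuration produce
byte-identical outputs.

What passing tests do not show: the generators produce geometry-plus-
community wiring with Bernoulli edges, not tractography artifacts,
site/scanner batch structure, heteroscedastic age-dependent noise, or
realistic gene-gene correlation; calibration and recovery results transfer
to real data only to the extent those ingredients do not dominate. The
published headline effect sizes (constraint r ≈ 0.74, prediction r
0.65–0.75, 2.3% backbone density at 1000 nodes) are properties of the
restricted empirical datasets and are not reproduced at desk scale; the
package reproduces the printed design arithmetic and the method's
qualitative behavior instead.
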