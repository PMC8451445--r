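---
title: "Classifying plant vulnerability to deer browsing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant vulnerability to deer browsing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deervuln)
```

## The analysis in one paragraph

deervuln asks, for every understory plant species observed across a
chronosequence of sika-deer establishment ages, two questions: *when* does
deer selection of this species begin (from the first years of
establishment, or only after preferred forage is depleted), and *what has
that selection done* to its cover?  Three evidence streams answer them —
plot-level coverage, browsing-damage scores, and fecal DNA metabarcoding —
each reduced to a per-species profile over the four establishment-year
classes, clustered by K-means with the gap statistic, and integrated by a
rule table into six vulnerability groups (A–F).  Everything stochastic is
seeded; one `(inputs, seed)` pair fixes every number the pipeline emits.

## Evidence streams and their models

### Mean damage grade

Ten plant units per species and site are scored into four ordinal classes
(CL1 no damage, CL2 1–10%, CL3 11–50%, CL4 51–100% of the plant damaged)
and summarized as `MDG = (0·CL1 + 5·CL2 + 30·CL3 + 75·CL4)/N ∈ [0, 75]`.
The weights make MDG roughly the expected percent of tissue removed, taking
each class at its midpoint-ish severity.  MDG is linear in class counts and
monotone under moving a unit to a more damaged class; cells where a species
was not surveyed stay `NA` and are excluded from every mean — absence of a
record is not evidence of zero damage.

### Read assignment

Fecal trnL P6-loop reads are assigned to a reference taxon only on exact
sequence identity.  The marker is short (~75 bp reads) and highly conserved
within species; with no published mismatch tolerance to emulate, exactness
is the conservative, reproducible choice.  Taxa whose reference sequences
are byte-identical are genuinely indistinguishable and are merged into one
taxon group that receives their reads jointly.  Unassigned reads are
conserved, never dropped silently: each lands in exactly one of
`too_short` (default `min_len = 20` nt — shorter fragments match by chance
too easily), `no_match`, or `low_frequency` (default `min_prop = 0.001` of
the sample's reads — below that, cross-sample index bleed and polymerase
error dominate).  Both thresholds are arguments, not constants, because
they are declared defaults rather than community standards.  Raising
`min_prop` can only remove counts (monotonicity), and per-sample totals
always satisfy assigned + unassigned = input.

### Community statistics

Site-level composition is the plot-summed coverage; dissimilarity is
Bray–Curtis throughout.  PERMANOVA partitions the Gower-centred `-D²/2`
matrix for a single factor with `p = (1 + #{F_perm ≥ F_obs})/(1 + B)`.  The
permutation engine is `vegan::adonis2`, but the permutation matrices are
generated by this package: seeded, optionally *exhaustive* (all `n! − 1`
non-identity permutations, for exact small-sample tests), and optionally
restricted to strata so labels never cross block boundaries.  Site must be
a block for the diet analysis because the 63 fecal samples are repeated
measures of 16 sites; a consequence worth knowing is that a factor constant
within sites (establishment class) is *untestable* under within-site
permutation — the blocked p-value is 1 by construction, which is precisely
the diagnostic that the factor's apparent effect could be site-level
confounding.  Dispersion homogeneity uses `vegan::betadisper` distances to
group centroids in principal-coordinate space with the standard
negative-eigenvalue correction.

NMDS minimizes Kruskal stress-1 with primary (within-tie averaging) tie
treatment via `vegan::monoMDS`; this package adds the multistart policy:
start 1 is the metric principal-coordinate configuration, starts 2…20 add
Gaussian jitter of growing magnitude (0.25·s times the configuration's
coordinate spread), and the best stress wins.  Twenty starts is the point
where, in our property tests, doubling starts stopped changing the reported
best stress on random dissimilarities.

dbMEM spatial eigenvectors use the classical PCNM construction
(`vegan::pcnm`): truncation at the longest minimum-spanning-tree edge,
distances beyond it replaced by four times the threshold, positive
eigenvalues retained.  "Detrended data" is implemented as residuals of the
response on the planar x, y coordinates before testing; each eigenvector is
then tested marginally by permutation of its R².  Forward selection with a
double-stopping rule is deliberately out of scope — with ~22 sites the
marginal tests are already at the resolution the data support.

GLM likelihood-ratio tests use the deviance difference for Poisson models,
which equals `2·Σ y·log(μ̂_full/μ̂_null)` with the `0·log 0 := 0` limit.
That form is exact when a group has all-zero counts, so no pseudo-count
offset is ever added.  Gaussian responses use the profiled log-likelihood.
A Laplace-approximated Poisson GLMM with a site random intercept
(`lme4::glmer`) is available as a fidelity mode for plot-level responses;
note its LRT for a between-site factor is deliberately more conservative
than the GLM's, because the null model can absorb group structure into the
site variance.

### Profiles and clustering

A species' profile is the 4-vector of class means of its site-level
statistic, always averaging sites within a class (and, for reads, samples
within a site first, so unevenly sampled sites are not over-weighted).
Coverage and MDG profiles keep only species observed in at least one site
of *every* class, so no class mean rests on zero observations; read
profiles keep every detected taxon.  The damage analyses cover species with
detected browsing (MDG > 0 somewhere) — a species surveyed and found
untouched carries no damage *evidence*.

Profiles are scaled before clustering.  The default divides each profile by
its own maximum, so clustering sees the *pattern* of variation across
classes rather than the species' abundance magnitude; `raw` and row
z-scoring are available because no scaling convention is universal, and the
choice is recorded in every clustering result.  This is the gravest
genuinely open choice in the pipeline, hence a surfaced knob rather than a
constant.

K is chosen by the gap statistic: `Gap(k) = mean_b log W*_kb − log W_k`
with B reference sets drawn uniformly over the data's per-dimension ranges
(the simpler of the two reference schemes; in 4 dimensions the PCA-aligned
box adds little), `s_k = sd_b(log W*_kb)·sqrt(1 + 1/B)`, and the smallest k
with `Gap(k) ≥ Gap(k+1) − s_(k+1)` selected (`cluster::clusGap`,
`Tibs2001SEmax`).  Degenerate inputs (all profiles identical, or too few
profiles for a gap curve) resolve to k = 1 rather than erroring, because a
small damage stream is a legitimate study outcome.  K-means itself is
`stats::kmeans` with 10–25 seeded restarts; a brute-force enumeration over
all bipartitions of small point sets confirms it reaches the optimum in the
regimes the tests cover.

### Integration into groups A–F

K-means labels are arbitrary, so clusters are mapped to meanings by
centroid shape, never index:

* a coverage cluster means **decline** iff its centroid's Y1978 (oldest
  establishment) value is both the minimum of the 4-vector *and* at least
  20% below the centroid's maximum.  The margin exists because a flat
  centroid's minimum lands on Y1978 a quarter of the time by noise alone;
  without it, every flat-coverage species would sporadically be read as
  declining;
* a damage or diet cluster means **early** selection if the centroid is
  already at ≥ 50% of its maximum in the youngest class (Y2014), **late**
  if it peaks at Y1978 while staying below 50% at Y2014, **other** for
  mid-peaking shapes, **none** for an all-zero centroid.

The rule table (editable CSV; `default_rule_table()`, a copy ships in
`inst/extdata/vulnerability_rules.csv`) then assigns, in order: early ×
decline → A; early × unknown-coverage → B; late × decline → C; late ×
unknown → D; flat coverage with no visible damage but diet evidence → E;
flat coverage with visible damage → F; anything else → `unclassified`,
retained with its full evidence tuple.  Three decisions here were genuinely
open and are encoded as defaults rather than claims:

* **"other" timing is routed with the late branch** — a mid-peaking signal
  still means selection began after establishment, just not monotonically;
* **E vs F**: species with both visible damage and diet evidence but no
  coverage response go to F (visible damage is the stronger evidence of
  browsing pressure); E is reserved for diet-only detections;
* **the G4 rule** (species absent from every oldest-class site but browsed
  elsewhere, which join the early branch with unknown coverage): the weak
  reading — browsed in at least one site of at least one other class — is
  the default, the strict all-three-classes reading sits behind
  `strict = TRUE`.

The species universe for classification is the union of the damage and diet
evidence streams; species in neither are excluded upstream, so the
partition "Σ group sizes + unclassified = universe" always holds.

## The synthetic generator

`sim_config()` encodes the emulated study design: 22 sites (5/4/4/9 per
class, oldest first) on a 300 × 200 km box with a class–longitude gradient
(the spatial-confounding structure a range expansion produces), 20 plots
per site on the 1%/5%-step coverage grid, 10-unit damage samples, 63 fecal
samples over 16 sites, negative-binomial read depth (mean 6,700,
dispersion 2, matching ~420k reads over 63 samples) plus 2% short junk
reads.  Where the emulated design fixes no value we chose once what a field
ecologist would call realistic and did not revisit it: 60 species
(8 A, 6 B, 8 C, 6 D, 5 E, 5 F, 22 neutral — enough per archetype for
centroid shapes to stabilize, small enough that a full pipeline run takes a
few seconds), per-plot occupancy 0.25, median occupied cover 20% with
lognormal spread 0.5, availability multipliers (0.15, 0.4, 0.7, 1) for
declining archetypes.

Damage classes are drawn from an ordinal logit with cutpoints (1, 2, 3.5):
a neutral linear predictor gives an expected MDG near 6, strong selection
(η ≈ 3) near 40.  Diet composition is Dirichlet-multinomial with
concentration proportional to selection weight × availability (total
concentration 30), so samples are realistically overdispersed relative to
multinomial.  Archetypes differ only through availability trajectories,
palatability (η) trajectories, and diet weights; `zero_effects = TRUE`
flattens all three into a permutation-null dataset.

What the generator does *not* emulate — and therefore what passing tests do
not establish about field data: sequencing error and chimeras (reads are
exact copies of reference sequences plus unambiguous junk), PCR
amplification bias beyond the all-or-nothing dropout planted for archetype
F, seasonal diet shifts, pre-establishment differences in community
composition between sites, and observer error in the damage scoring.  The
recovery rates the tests report are properties of the pipeline under the
planted model, not field-accuracy estimates.

## Numerical choices and problem sizes

Tolerances: IRLS to `glm`'s default convergence with a 100-iteration cap;
NMDS stress ratio `1 − 1e-7` with 200 iterations per start; matrix CSV
round-trips hold to 12 significant digits (15 are written).  Ties: isotonic
regression uses within-tie averaging; `which.min`/`which.max` tie-breaks in
centroid semantics take the first (oldest-class) position, which only
matters for exactly-equal centroid coordinates.  Degenerate inputs resolve
rather than crash wherever the degenerate case is a legitimate outcome
(k = 1 clusterings, all-unassigned samples warn, empty classifications
report "no species classified") and error where it signals corrupt input
(zero-N damage records, conflicting reference sequences, duplicate
coordinates in dbMEM).

The test suite validates at deliberately desk-scale sizes: exhaustive
PERMANOVA enumeration at n ≤ 7; type-I error at n = 30 over 500 null
simulations with 199 permutations; gap-statistic selection over 100 seeded
runs with B = 25; end-to-end archetype recovery over 50 replicate studies
at the default design with 50 reference sets; null-calibration of the
vegetation PERMANOVA over 100 zero-effect replicates.  The acceptance
script uses 999 permutations for the single showcase run and 20 replicates
for the recovery estimate.

## Known limitations

The exact-match assigner will under-assign real reads with sequencing
errors; it is the right tool for the planted-truth simulations and a
conservative baseline for real data.  The MDG-versus-coverage regression is
exposed through `glm_lrt`'s Gaussian/log-link option but its response
transformation is left to the user — the source analyses are ambiguous on
this point and it feeds no downstream decision.  The dbMEM check tests
vectors marginally, so it bounds, rather than removes, spatial confounding.
Establishment class is observational: with deer spreading along a
geographic gradient, class effects and pre-existing site differences are
not separable by design, only flagged — which is exactly why the site-blocked
diet PERMANOVA and the dbMEM check are part of the pipeline.
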