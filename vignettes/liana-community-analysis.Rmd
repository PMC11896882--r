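---
title: "Methods: liana community structure, composition and host specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liana community structure, composition and host specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`lianascape` is an analysis workflow for quadrat-based liana censuses in
closed tropical forest. The scientific question it serves is how much of the
structure (stem density, basal area, mean size), floristic composition and
functional composition of a liana community is predictable from the local
forest around it — stand structure, canopy height, giant-herb cover,
microtopography — and how much instead reflects taxon-specific associations
between lianas and their host trees.

Because raw stem-level census data of this kind are rarely public, the
package ships a synthetic census generator whose defaults reproduce the
design and headline statistics of a Central African field campaign: four
9-ha plots (300 × 300 m) each holding 36 liana quadrats of 20 × 20 m
(4 per ha, 50-m centres), every quadrat carrying a 10-m buffer so tree-side
variables are measured on 40 × 40-m windows; trees ≥ 10 cm DBH in two
censuses; all lianas ≥ 1 cm diameter; a 10-m giant-herb cover lattice
(100 points/ha); and a 1-m terrain model dotted with large termite mounds.
Every analysis stage is then validated against that generator: calibration
under a neutral world, power against planted signals, and exact oracles
where a closed form or an independent implementation exists.

# The synthetic world

## Terrain and canopy

The DEM is a Gaussian-filtered white-noise background (bandwidth 40 m)
rescaled to a configurable relief (`base_relief`, default 12 m — the real
site varies by about 23 m *between* plots and much less within), plus
Gaussian bumps at Poisson locations for termite mounds: density 2.25/ha
(the field range is 1.5–3), radius ~ N(9.9, 3.3) m, height ~ N(4.1, 1.5) m,
the bump's standard deviation set to half the radius so the mound visually
ends near its nominal radius. The DSM adds a canopy-height field — again
filtered noise, bandwidth `canopy_smooth` = 8 m, rescaled to [0, 45] m —
with circular gaps (fraction 0.05 of the area, radius ~10 m) where canopy
height drops to under a metre. The canopy model is deliberately the
simplest field with tunable autocorrelation; no attempt is made to couple
canopy to tree positions, so a green test establishes the statistics of the
estimators, not realism of gap dynamics.

## Trees, herbs, lianas, traits

Tree stems are uniform in space (density 450/ha), species drawn from a
sorted symmetric Dirichlet profile (concentration 0.5 for trees), DBH from
a shifted exponential with mean 25 cm, which gives a stand basal area near
30 m²/ha. Census 2 applies growth (N(0.5, 0.4) cm, floored at 0), 2%
mortality and 3% recruitment, so the basal-area change ΔBA_T varies among
windows.

Giant herbs sit on the 10-m lattice with an ordered-probit cover index in
{1, 2, 3}: the latent mean decreases with local canopy height at rate
`herb_coef` (default 0.08 per m), encoding that these light-demanding herbs
favour gaps; with the coefficient at zero the index is exactly the
configured base distribution.

Liana counts per quadrat are Poisson with a log-linear mean in the
standardized environment, coefficients `beta_structure` (defaults signed as
observed in the field: negative effects of tree size, canopy height, wood
density, basal-area change and herb cover on abundance), normalised so the
realised mean density matches `liana_density` = 1077 stems/ha. Taxa come
from a sorted Dirichlet with concentration `dominance` = 0.08, which at 82
taxa gives an expected top-3 share near the 54% hyperdominance observed in
the field; each taxon also carries niche coefficients (`env_response`, sd
0.3 by default) that tilt its local probability. Diameters follow a shifted
two-component exponential mixture (weight 0.63 on rate 1.4, 0.37 on rate
0.5, +1 cm, truncated at 27 cm) calibrated once to the two published
quantiles — 62% of stems in 1–2 cm and ~94% in 1–5 cm; the census reports
no fuller distribution, so nothing else about stem sizes should be read as
realistic. Each liana picks a host among the tree stems of its buffered
window with probability proportional to `theta_host[taxon, species]`
(log-normal weights, sdlog 0.5 by default; all-ones is the neutral world),
and 10% get a second host. Lianas are located only to their quadrat — the
real inventory is quadrat-based — so host choice, not stem position, is the
spatial unit below the quadrat.

Traits (leaf thickness, SLA, %C, %N, %PO4, %K, stem tissue density) are
drawn inside the published ranges via a probit transform of a latent value
correlated at `trait_niche_cor` (default 0.5) with the taxon's
canopy-height niche coefficient — positively for conservative traits
(tissue density, carbon, thickness), negatively for acquisitive ones (SLA,
PO4, N, K). Only the 44 most abundant taxa are covered, mimicking an
incomplete trait campaign (95% of stems in the field).

A single integer seed drives every draw; regenerating with the same
configuration is bit-for-bit identical, which the test suite asserts.

# Quadrat-scale metrics

Liana structure per 20-m quadrat: abundance N_L (stems/ha = count × 25),
basal area BA_L (Σ π(d/200)² × 25, m²/ha), quadratic mean diameter QMD_L
(√mean d²; undefined and flagged in empty quadrats). Tree-side variables on
the 40 × 40-m window, from the census contemporaneous with the liana
inventory: N_T, BA_T, QMD_T, WD_T (unweighted stem mean — the field
description says "tree mean wood density" without a weighting, so the
unweighted mean is the default and a weighted variant would be a one-line
change), and ΔBA_T in absolute m² (not per ha). meanTCH is the window mean
of the canopy height model (DSM − DEM, negatives clipped). GHFC averages
the nine herb points of the quadrat; incomplete quadrats are averaged over
what is present and flagged.

## Relative slope position

RSP = AACL / (AACL + ABRL): the altitude above the channel network divided
by the total local relief between channels and ridges, 0 on channels, 1 on
ridge and mound summits. The field study derived it with a GIS toolbox;
here it is rebuilt from first principles so the whole chain is testable:
pits are filled, D8 steepest-descent directions are computed, flow is
accumulated in decreasing elevation order, and cells draining at least 1%
of the grid become channels; each cell's AACL is its elevation minus that
of the channel cell its D8 path reaches (outlets without a channel act as
their own). ABRL applies the identical construction to the inverted DEM, so
by symmetry RSP(−DEM) = 1 − RSP(DEM), which is asserted in the tests. The
degenerate 0/0 case (a cell that is both channel and ridge) is defined as
0.5. The 1% channel threshold is a scale choice, not a hydrological claim:
only relative position within the mound-to-drainage relief matters here.

# Structure models

Responses N_L, BA_L and QMD_L are modelled on the eight standardized
predictors. Pseudo-replication from the nested design (quadrats in 1-ha
blocks in 9-ha plots) is checked first: a profile-REML random-intercept
model per grouping level, with LR = REML criterion at zero variance ratio
minus the criterion at the optimum — evaluating the same criterion function
at θ = 0 guarantees LR ≥ 0 and identical constants — and a plain χ²₁
p-value, which is conservative for a variance component on the boundary (no
50:50 mixture correction, matching the source procedure's description).
Model selection is greedy stepwise in both directions from the full model
under Gaussian AIC = n log(RSS/n) + 2(k + 1); exact ties break toward fewer
predictors. The greedy search is checked against exhaustive subset
enumeration on small designs. Wald 95% intervals are reported (the source
does not say whether its intervals are profile or Wald).

# Ordination

NSCA treats sites as rows: with P = A/total, row masses r and column
masses c, it decomposes q_ij = p_ij/r_i − c_j under the row metric diag(r)
and the *identity* column metric, so the inertia Σ_i r_i Σ_j q_ij² weights
squared deviations by abundance rather than chi-square-scaling them —
abundant taxa matter more, rare taxa are not inflated. NSCAIV projects the
deviation table onto the span of the standardized predictors under the
row-weight metric and permutes predictor rows (999 by default) to test the
explained fraction. PCCA is classical chi-square CCA with a conditioning
table — the centred second-order polynomial of quadrat coordinates —
partialled out of both the response and the design by weighted regression;
with an empty conditioning table it reduces exactly to CCA, which is
verified against an independent CCA implementation to 10⁻⁸. Axis signs are
fixed by making the largest-|loading| taxon positive. Directions of the
constrained design that are numerically absorbed by the conditioning table
(relative column norm below 10⁻⁸) are dropped rather than projected on, to
avoid resurrecting noise axes.

Spatial structure of axis scores is tested with permutation variograms:
semivariance per equal-width distance class (11 classes to the maximum
inter-quadrat distance; bin edges are not published, so equal width is the
package's choice), a pointwise 95% envelope from 9999 permutations of
scores over locations using order statistics at ranks ⌈0.025(n+1)⌉ and
⌊0.975(n+1)⌋, and per-class two-sided permutation p-values. Empty classes
merge rightward with a logged message.

# Trait–environment tests

CWM (trait averaged over a site's taxa by abundance) and SNC (environment
averaged over a taxon's sites by abundance) regressions are weighted by
Hill numbers of order 2 — the effective number of taxa in a site (for the
site-level test) or of sites for a taxon (species-level test) — so
abundant, well-estimated units count more. The site-level test permutes
environment values over sites with CWM fixed; the species-level test
permutes trait values over taxa with SNC fixed; the reported p is the
maximum of the two, which is conservative by construction and protects
against signal carried by a single dominant taxon or a single site. The
test statistic is the absolute N2-weighted correlation, equivalent under
permutation to the weighted-regression slope.

The reported fourth-corner correlation standardizes the trait over taxa
with abundance weights and the environment over sites with abundance
weights, takes the CWM of the standardized trait, and correlates it with
the standardized environment using Hill-N2 site weights. The exact
weighting convention inside published N2-weighted fourth-corner tables is
not restated in the source; this definition is documented as the package's
choice, is affine-invariant in both trait and environment (asserted to
10⁻¹⁰), and its null calibration — not its numerical match to any published
table — is what the acceptance battery verifies.

The trait-shuffle null for CWM–axis correlations randomizes trait values
among taxa (999 shuffles), recomputes CWM each time, and uses a two-sided
count of |r|; with a constant trait the observed and null statistics are
all zero and p = 1 by the (1+exceed)/(1+n) convention, which every
permutation test in the package shares so no p can be zero.

# Host specificity

The RV coefficient between column-centred liana and tree abundance tables
(trace(XᵀY YᵀX) normalised by the table norms) is tested by permuting the
rows of one table; the environment-residualized variant applies the same
test to the NSCAIV residual tables of both communities, i.e. to the
compositional variation the measured environment does not explain. Row
weights for the co-inertia step are uniform: the two tables have different
natural weightings and the source does not specify a common one.

The randomization test redraws, for each liana–host link independently, a
host uniformly among the tree stems of that link's buffered window (999
replicates), preserving per-quadrat, per-taxon link counts — so spatial
aggregation of taxa cannot masquerade as host preference. Envelope bounds
are the order statistics at ranks 25 and 975, giving integer bounds;
attraction means observed strictly above the upper bound, repulsion
strictly below the lower, bounds inclusive ns. The unit of randomization is
the link (a two-host liana contributes two draws); trees are drawn
unweighted by size; a link may redraw its observed host. Liana taxa need
more than 60 individuals and tree species more than 100 stems to be
reported — the source states "> 60" in its methods and "≥ 50" in a table
note; the methods value is the default and both filters are arguments.

# Numerical and testing choices

* Permutation p-values are always (1 + exceedances)/(1 + n permutations).
* The 0/0 cases are pinned: RSP 0.5, fourth-corner r of a constant trait 0.
* Quadrat membership is half-open ([min, max)) so boundary stems belong to
  exactly one quadrat; the herb lattice uses closed bounds so a 20-m
  quadrat holds its full 3 × 3 block of points.
* Calibration tests run the whole battery at reduced size (15–24 sites,
  99–199 permutations, hundreds of replicates) to keep the suite inside a
  desk-scale budget; replicate counts were sized so the Monte Carlo
  standard error of each rejection rate is well under the ±2-percentage
  point acceptance band.
* The greedy stepwise search can in principle miss the AIC-optimal subset;
  the suite checks ≥ 90% agreement with exhaustive enumeration on 5
  predictors rather than pretending the greedy search is exact.

# Known limitations

The canopy field is not generated from the simulated trees, so
canopy–stand correlations in the synthetic world are weaker than in real
forests; liana stems have no within-quadrat coordinates; there is no
seed-dispersal, clonality or growth dynamics, so the two tree censuses are
the only temporal signal; the trait generator couples every trait to a
single (canopy-height) niche axis, not to a full multivariate niche; and
the published data-dependent results (model R² values, explained-inertia
percentages, specific fourth-corner entries, the field RV values) are not
reproducible without the field data — the acceptance battery deliberately
replaces them with calibration, power and oracle properties that the
synthetic world can actually decide.
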