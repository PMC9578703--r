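---
title: "Methods: diversity, spatial structure, and homogenization of city tree communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, spatial structure, and homogenization of city tree communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbancanopy)
```

`urbancanopy` treats municipal street-tree inventories as samples of
ecological communities and asks three questions of them: how diverse is a
city's tree community once sampling effort is controlled for; are trees
arranged in space at random with respect to species, or clustered into
same-species patches; and do cities' tree communities resemble each other
because of a shared pool of introduced species. This vignette records the
models behind each answer, the tunable parameters and why their defaults
are what they are, what the synthetic-city generator does and does not
emulate, and the numerical conventions adopted where a choice had to be
made.

## The data model

An inventory is one row per tree with a standardized vocabulary:
`location_type` is the dichotomy *green space* versus *built environment*
(anything else becomes `unknown`), `condition` is a six-point descriptive
scale (`excellent` … `dead_dying`) harmonized from each source city's own
scoring via a per-city `condition_map()` — source inventories use
incompatible scales, so harmonization is configuration, not code — and
`native_status` is `naturally_occurring` / `introduced` / `no_info`.
Records identified only to genus (a single-token scientific name) carry no
nativity evidence and are forced to `no_info`. Rows with impossible
coordinates are retained in the table but flagged and excluded from all
spatial operations. For condition modelling the descriptive scale collapses
to a binary: `excellent`/`good`/`fair` → 1, `poor`/`dead`/`dead_dying` → 0,
`unknown` → missing.

## Effective species and size standardization

Diversity is the effective species count, the exponential of Shannon
entropy over species frequencies $p_i$:

$$D = \exp\Big(-\sum_{i=1}^{n} p_i \ln p_i\Big),$$

bounded between 1 (monoculture) and $n$ (the richness, attained exactly at
uniform frequencies). It is preferred over raw richness because it weights
species by their abundance: a city with 200 recorded species of which five
dominate is, effectively, a five-ish-species forest.

Inventories range over three orders of magnitude in size, and $D$ estimated
from more trees is systematically larger. Comparisons therefore use
**Monte-Carlo size standardization**: subsample a fixed number of trees
without replacement, compute $D$, repeat (default 500 replicates), and
report the mean with a 2.5–97.5% percentile interval over replicates. The
conventional standard sizes are 37,000 trees for all-species comparisons
and 10,000 for naturally-occurring-only comparisons (round median inventory
sizes); park-versus-urban comparisons inside one city standardize both
strata to the smaller stratum's size and then pair the per-city differences
in a t-test. When the requested size exceeds the community, rarefaction is
impossible; the estimate falls back to resampling with replacement and is
flagged `extrapolated` — asymptotic richness estimators (the Chao family)
are deliberately out of scope, as subsampling serves the same standardizing
purpose without a closed-form dependency. Subsampling is implemented by
drawing tree indices (`sample.int`) and tabulating, so a 500-replicate
standardization of a 45,000-tree city costs well under a second.

## Clustering by species

The spatial question is whether the trees of a city are a random spatial
shuffle of its species list. The procedure:

1. Project coordinates to UTM (single zone per city, chosen from the
   centroid — intra-city distances are what matter, and a zone seam through
   a city would distort them more than one consistent zone does). The
   projection is the standard WGS84 transverse-Mercator series, implemented
   in the package and verified against geodesic distances; no external
   projection library is required.
2. Cluster all trees with HDBSCAN: `min_cluster_size = 30`,
   `min_samples = 10`, Manhattan metric, excess-of-mass extraction.
   Manhattan distance respects the block geometry of cities — two trees
   across a city block are close as the crow flies but far along streets.
   Points in low-density areas are labelled noise and excluded. HDBSCAN is
   implemented in the package: core distances and the mutual-reachability
   minimum spanning tree in C++ (exact, $O(n^2)$, no spatial index — a
   45,000-point city is seconds), hierarchy condensation and
   excess-of-mass selection in R. The implementation was checked against an
   independent reference implementation on fixtures (identical partitions on
   blob and street-grid geometries).
3. Score each cluster: observed $D$ of the cluster's trees over the median
   $D$ of 500 equal-size draws (without replacement) from the whole city,
   as a percentage. 100% means the cluster is compositionally a random
   sample; below 100% means same-species aggregation. Drawing without
   replacement makes the identity case exact: a "cluster" containing the
   entire city scores precisely 100%.
4. Summarize a city by the median ratio across clusters with a 10,000-rep
   percentile bootstrap CI of the median (resampling clusters); the city is
   *significantly clustered by species* when the CI's upper bound is below
   100%. Cities with fewer than 11 clusters are excluded as under-sampled:
   a median and its bootstrap CI over ten or fewer clusters are too
   unstable to support a city-level claim.

Numerical conventions worth recording: the ratio is oriented
observed/expected (values < 100% = aggregation); the reverse orientation is
available via a flag because the two conventions coexist in the literature.
`cluster_selection_epsilon` defaults to 0.0004 for comparability with
prior street-tree clustering analyses, but note its units are those of the projected
coordinates — 0.4 mm in UTM meters, hence effectively inert; it is an
exposed parameter rather than a hidden constant, and the calibration tests
rely on geometry, not on this value. Zero-length mutual-reachability edges
(duplicate coordinates) are floored at $10^{-12}$ m before inverting to
density so the condensed tree stays finite.

## Spatial coverage

How uniformly an inventory samples its city is audited on a 0.005° × 0.005°
grid anchored at the minimum latitude/longitude (of the boundary polygon if
one is supplied, else of the points), with half-open `[low, low + cell)`
membership so edge trees are assigned deterministically. With a boundary,
cells are clipped (Sutherland–Hodgman) and a cell's `area_fraction` is its
in-boundary area over the largest such area; the adjusted count is
`raw × area_fraction` — the printed down-weighting convention; a density
option (`raw / area_fraction`) is available but non-default. Water-feature
exclusion is delegated to the boundary polygon; no hydrography is bundled.
The report is the percent of empty cells plus skewness
$g_1 = m_3/m_2^{3/2}$ and kurtosis $b_2 = m_4/m_2^2$ of adjusted counts
over occupied cells — central-moment ratios without bias correction,
kurtosis non-excess (normal = 3), matching the convention of the classical
`moments` functions. Fewer than two occupied cells, or zero variance,
leaves the moments flagged undefined rather than zero.

## Community similarity and homogenization

Between-city similarity is chi-square similarity over the union of species
(species absent from both cities are dropped — the 0/0 guard):

$$S(x, y) = 1 - \frac{1}{2}\sum_{i=1}^{n}\frac{(x_i - y_i)^2}{x_i + y_i},$$

1 for identical compositions, 0 for disjoint pools. Unequal city sizes are
standardized by subsampling the larger city without replacement to the
smaller's size, 50 times, reporting the **median** similarity (equal sizes
compare exactly, once).

Homogenization is tested by computing, for every city pair, similarity
under two conditions — all trees, and naturally occurring trees only — and
pairing the differences: a paired t-test (df = pairs − 1) backed by a
Wilcoxon signed-rank test (exact for ≤ 25 pairs, normal approximation with
tie correction beyond). A positive mean difference says introduced species
make cities look more alike than their native communities are.

Environmental similarity comes from a PCA of the 19 bioclimatic variables
(centered, unit variance; each component's sign fixed so its
largest-magnitude loading is positive, since PCA signs are otherwise
arbitrary). Similarity is one minus the Euclidean distance in (PC1, PC2)
normalized by the maximum pairwise distance, so the most dissimilar pair
scores exactly 0. Two components are the default — with 19 strongly
collinear climate variables they carry nearly all the variance, and the
similarity stays interpretable as distance in the standard two-component
climate plot; `n_pc` exposes the all-components alternative. Whether environment predicts native
communities more strongly than all-species communities is a comparison of
two overlapping dependent correlations, tested with Pearson–Filon's z
(implemented directly from the published statistic; with fewer than four
pairs the report carries a low-n flag and no p-value).

## Nativity

A species is naturally occurring in a state if its normalized binomial
appears in that state's reference flora (CSV of `state, taxon` rows);
resolvable binomials absent from the list are introduced; genus-only
records are `no_info`. Normalization strips cultivar epithets and
infraspecific ranks down to the binomial (reference floras are
binomial-level) but keeps hybrid markers — a hybrid absent from the flora
is introduced, not unknown. Percent native is computed over classified
trees by default: genus-only records carry no evidence either way, so
putting them in the denominator would bias the percentage downward in
cities with sloppy species columns; a flag switches to the all-trees
denominator for sensitivity. For each introduced species the summary also
records whether its genus contains any naturally occurring species in that
state (a native congener) — relevant because congeneric natives often
support similar insect communities.

## The synthetic-city generator

Every analysis stage is exercised against cities with known truth, built
by `simulate_city()` / `simulate_city_set()`:

- **Geometry.** A square city (default 0.06°, ~6.6 km) crossed by a
   12 × 12 street grid, with three rectangular parks totalling 15% of the
  trees (`green_space`); the rest line streets. Street trees are placed *by
  block* — each street segment between crossings is planted with
  probability 0.5 and planted blocks get log-normal intensities — because
  real inventories are strongly block-structured, and it is this density
  heterogeneity that gives a density-based clusterer genuine structure to
  find (a uniformly planted grid would be one density-connected component).
- **Abundance.** A geometric rank-abundance series: rank-$k$ weight
  $\propto$ `abundance_shape`$^{k-1}$, default 0.85 over 40 species — the
  simplest skewed abundance model, with shape 1 recovering uniform
  frequencies exactly.
- **Spatial aggregation.** With probability `mixing_rho` a tree copies the
  species of its nearest already-planted neighbour instead of drawing from
  the series. This one knob moves the city continuously from
  species-random (`rho = 0`, cluster ratios calibrated at 100%) to fully
  aggregated (`rho = 1` degenerates to a single species sweeping the city).
  Nearest-neighbour copying was chosen over a Markov random field because
  it is fast, order-randomized, and monotone in an interpretable way.
- **Nativity and city sets.** Nativity is a species-level property: trees
  draw from a native or a shared introduced pool with probability
  `native_fraction` (default 0.5, near the median percent-native of real
  inventories). City sets share the introduced pool while native pools are
  per-city; `native_overlap_span` places native pools as windows along a
  latent climate gradient so climatically close cities share more natives,
  and the 19 fabricated bioclim variables are linear in the same gradient
  plus noise. With disjoint native pools the construction forces the
  homogenization signal: all-species similarity strictly exceeds
  native-only similarity in expectation.

What the generator does **not** emulate: real street networks (no curves,
no density gradients from downtown to suburbs), taxonomic error and
synonymy, condition–location correlations, within-species spatial scales
other than nearest-neighbour contagion, and inventory sizes beyond ~10⁴
(tests run at 5,000 trees per city). Passing tests therefore demonstrate
calibration and directional correctness of the estimators under controlled
violations, not that any particular real city is well described by the
generator.

## Test problem sizes and determinism

The calibration checks run twenty 5,000-tree cities at `rho = 0` (the CI
for the median cluster ratio must cover 100% in at least 90% of them),
twenty at `rho = 0.9` (detection in at least 90%), ten seeds at each of
`rho ∈ {0, 0.5, 0.9}` for monotonicity, and a ten-city set (45 pairs) for
the homogenization direction — sizes chosen so the full suite runs in
minutes on one core while leaving Monte-Carlo error well inside the
asserted margins. Every stochastic routine takes a `seed` argument,
restores the caller's RNG state on exit, and is byte-reproducible given the
seed; the pipeline derives per-city sub-seeds from one master seed so runs
are reproducible end to end.

## Known limitations

- $O(n^2)$ clustering memory/time is fine up to ~10⁵ trees per city but
  would need a spatial index beyond that.
- The UTM single-zone-per-city convention mildly distorts east–west
  distances for cities near zone boundaries (scale error < 10⁻³).
- Chi-square similarity over frequencies ignores species identity beyond
  presence/abundance — phylogenetic or functional similarity is out of
  scope.
- The paired t-test across city pairs inherits the usual caveat that the
  45 pairs from 10 cities are not mutually independent; the Wilcoxon
  backup shares it. The package reports the conventional tests rather than
  a dependence-corrected alternative.
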