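---
title: "Methods: conservation gap analysis, niche overlap and phylogenetic signal in gapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation gap analysis, niche overlap and phylogenetic signal in gapkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gapkit quantifies how well the germplasm held in genebanks represents the
geographic and ecological range of wild taxa — typically crop wild
relatives — and, alongside that, how strongly related taxa share ranges and
environmental niches.  This vignette is the package's account of the
models, the tunable constants, the numerical choices, and the points where
the design was genuinely open.

## The data model

All spatial work happens on a `grid_layer`: a north-up lattice of square
cells in geographic coordinates, with `NA` for missing cells.  Layers are
only ever combined when their shape, origin and cell size match exactly;
nothing is resampled silently.  Raster I/O uses the plain-text ESRI ASCII
grid dialect.  Cell areas follow the cosine-latitude rule on a sphere of
radius 6371 km, and all point-to-point distances are haversine distances on
the same sphere.  At the ~50-km scale that drives every score here, the
spherical approximation errs by well under 1%, and it keeps every quantity
hand-checkable — an ellipsoid would change no decision the package makes.
Rows with cell centres poleward of 89.5° are rejected rather than given
near-zero areas.

Occurrence records carry a taxon, a record type — `G` for germplasm
accessions (genebank samples), `H` for reference records (herbarium
vouchers and the like) — and optionally coordinates.  Records with
unparseable or out-of-range coordinates are kept with coordinates blanked:
they still count toward sampling representativeness, just not toward any
map.  Duplicates are records agreeing on taxon, type, and coordinates
rounded to 4 decimals (≈11 m); type is part of the key deliberately, so a
genebank accession never erases a herbarium voucher from the same site —
the conservative direction for the sampling score.  The source data for
such analyses rarely state a duplicate rule; this one is ours and the
rounding is configurable.

## Potential distributions: validated models with a buffer fallback

gapkit does not fit distribution models.  It evaluates suitability
surfaces produced elsewhere (or by the synthetic generator) and decides,
per taxon, between two routes to a presence/absence range:

1. **Model route.** Five cross-validation folds give five test AUCs
   (rank-based, ties counted half, against background points — 10,000 by
   default).  The model is accepted iff the fold-average AUC (ATAUC)
   exceeds 0.7, the sample standard deviation of the fold AUCs (STAUC) is
   below 0.15, and the ASD15 stability criterion holds.  An accepted
   surface is binarised at the threshold that maximises sensitivity plus
   specificity over the observed presence and background scores, with ties
   resolved to the lowest candidate (the most inclusive range).
2. **Buffer route.** Otherwise — including when no surface exists at
   all — the range is the union of 50-km circular buffers around the
   taxon's occurrence points (the CA50 distribution).

ASD15 is implemented two ways because its printed definition ("at least
10% of cells with across-fold SD below 0.15") is much weaker than the
variant common in the literature (at most 10% of cells with SD *above*
0.15).  The literal reading is the default; `asd_rule = "strict"` switches
to the other.  We do not guess which was intended — both are first-class.

Buffer membership is decided at cell centres, not by polygon
rasterisation.  That choice is ours (sources typically do not say), it is
documented, and the radius and rule are configurable.  Excluded land cover
(urban, water, bare, ice) enters as a 0/1 mask whose cells become missing
in every downstream layer, area and count.

## The representativeness scores

For each taxon, with `n_G` germplasm and `n_H` reference records:

* **SRS** `= 10 · n_G / (n_G + n_H)` — all records count, mapped or not.
* **GRS** `= 10 · area(buffers ∩ range) / area(range)` — the share of the
  potential distribution within 50 km of a germplasm collection, using
  cosine-latitude cell areas; coordinate-bearing germplasm only.
* **ERS** `= 10 · |classes(buffers ∩ range)| / |classes(range)|` —
  ecosystem classes are counted as present or absent, not area-weighted:
  ecological representativeness is about *kinds* of environment sampled.
* **FPS** is the plain mean of the three, and the priority bands are
  half-open intervals matching the conventional printed ranges: FPS in
  [0, 3] → high priority (HPS), (3, 5] → medium (MPS), (5, 7.5] → low
  (LPS), (7.5, 10] → no further collecting required (NFCR).

The ×10 scaling exists because the bands are stated on a 0–10 scale while
the SRS sentence alone reads as a 0–1 ratio; the bands win.  ERS has no
universally printed formula; the class-counting form implements the
standard gap-analysis methodology and is flagged here as a reconstruction.
All three scores are provably monotone under added germplasm, and the test
suite exercises that property on random worlds.

## Range and niche overlap

For each unordered taxon pair (n taxa give exactly n(n−1)/2 rows):

* geographic overlap from the binary ranges: shared cells, the Sørensen
  fraction `2|A∩B|/(|A|+|B|)`, overlap relative to the larger range
  `|A∩B|/max`, and relative to the smaller `|A∩B|/min`.  The "relative to
  the smaller range" formula circulating in print is garbled; we compute
  `shared/min(|A|,|B|)` and report the Sørensen form alongside so nothing
  is lost.  A pair is sympatric when it shares at least one cell at the
  analysis resolution (threshold configurable).
* niche overlap from occupancy distributions: both surfaces (continuous
  suitability where the model was valid, uniform-over-range otherwise) are
  normalised to sum to one over their *shared* valid cells, then
  Schoener's `D = 1 − ½Σ|p−q|` and the Hellinger-based
  `I = 1 − ½Σ(√p−√q)²` (identically the Bhattacharyya coefficient
  `Σ√(pq)`).  `D ≤ I` always; the suite fuzz-tests both identities.

Cohort summaries report, per group of pairs (all, annual, perennial,
allopatric, sympatric, sister), the percentage with near-perfect overlap,
with D or I above 0.5, and with D or I below 0.2 (divergent niche).
"Perfect" is nowhere defined in the tables this format imitates; the
default rule is `max(D, I) ≥ 1 − 1e−6`, the knob is exposed, and the rule
used is attached to the output.  Range asymmetry is the mean of
(smaller-range overlap − larger-range overlap) over sympatric pairs, in
percentage points.  Per-variable niche envelopes are the middle 90% of
occurrence values (5th–95th percentile, interpolated order statistics).

## Environmental typology and phylogenetic signal

Occurrence points are attributed with each environmental layer
(containing-cell lookup; points on missing cells are dropped and counted),
standardised, and ordinated by PCA.  A deterministic sign convention — the
largest-magnitude loading of each component is made positive — removes the
platform-dependent sign flip of eigenvectors.  Ward (`ward.D2`)
agglomeration on the first three component scores, cut at three clusters,
assigns each taxon by majority vote of its points (ties to the lowest
cluster id).  Three and three are defaults, not magic: they reflect the
usual aim of separating broad ecosystem types, and both are configurable.

Per-taxon traits are the medians of those extractions (mean available);
taxa with fewer than three usable points are excluded from clustering and
signal estimation with a warning — their summaries are too unstable to
carry inference.

**Blomberg's K** is computed from the phylogenetic covariance matrix C
(shared branch lengths) as the ratio of observed to Brownian-expected
mean-square error, with the generalised-least-squares phylogenetic mean:
on a star tree with equal branches it equals 1 exactly for *any* trait
vector, and it averages 1 under Brownian motion — both are verified in the
tests, along with agreement (to 1e−6) with an independent reference
implementation.  Significance comes from 1000 tip-label permutations of
the rate statistic 1/MSE, with the +1 correction so p is never zero.  The
accompanying figure convention in the literature flags "K significantly
greater than 1"; the permutation test is what the cited implementation
actually performs, so both decision rules are exposed and the conservatism
summary defaults to `p < 0.05` (switchable to `K > 1 ∧ p < 0.05`).

The **Mantel test** correlates the off-diagonal entries of two distance
matrices and permutes rows/columns of one of them, one-sided for positive
association, again with the +1 correction.  Three distance builders are
provided — Mahalanobis on the trait table (pooled covariance, ridge
1e−8 if singular), great-circle between taxon occurrence centroids, and
cophenetic path length on the tree — because published uses of "a Mantel
test with Mahalanobis distance" underdetermine which pair was compared;
the pipeline's default pairs environmental (Mahalanobis) distance with
cophenetic distance, and none of the builders is privileged in the API.
Raw permutation p-values drive the summaries; Benjamini–Hochberg adjusted
values are reported alongside in `ksignal.csv`.

## The synthetic world: what it emulates, what it does not

`make_world()` replaces the real inputs (climate and soil rasters,
ecoregion maps, genebank/herbarium occurrences, a sequence-derived
phylogeny) with a seeded generator whose truth is known:

* **Environment** — white noise smoothed by a moving average
  (`correlation_length` 7 cells) and standardised; layers share three
  latent fields with a 0.3-weight private component, because real
  bioclimatic predictor sets are strongly inter-correlated and analyses
  of them (PCA especially) behave very differently on independent fields.
* **Taxa** — 36 taxa whose niche optima evolve by Brownian motion on a
  random coalescent (ultrametric) phylogeny, then are standardised per
  variable (a linear map, so the phylogenetic structure survives).  Niche
  breadths are log-normal around 0.8 environmental SD — narrow enough
  that taxa differ and ranges are finite, broad enough that ranges
  overlap, which is the regime the analyses are about.  Suitability is
  the Gaussian niche response `exp(−½Σ((env−centre)/breadth)²)` rescaled
  to maximum 1 — a documented surrogate standing in for a fitted
  distribution model, since everything downstream consumes any
  suitability surface.
* **Records** — each taxon draws 40–200 records; 37% carry coordinates
  (sampled without replacement across cells, probability proportional to
  suitability, jittered within the cell) and the rest are deliberately
  coordinate-free; a per-taxon germplasm share between 5% and 60% flags
  records `G`.  These proportions mirror the typical shape of pooled
  genebank + herbarium datasets, where most records are not mappable.
* **Context** — ten Voronoi-patch ecoregion classes, a compact excluded
  blob covering 5% of cells, and an annual/perennial label per taxon.
* **Model folds** — fold surfaces are the true suitability plus clamped
  Gaussian noise (SD 0.08), giving a realistic mix of taxa that pass and
  fail validation.

The default grid is 60 × 60 cells of 0.25°; at that size the full
36-taxon pipeline, including 1000-permutation statistics, runs in well
under a minute, and the test suite's simulation studies (200 Brownian
replicates at 50 tips; 1000 null Mantel simulations) stay comfortably
inside a desk-scale budget.  Those problem sizes are choices, stated here
so they can be revisited deliberately rather than drifted.

What the generator does **not** emulate: anisotropic or trended climate
fields, spatial sampling bias (roadside collecting), taxonomic
misidentification, coordinate error beyond cell jitter, non-Gaussian or
multimodal niches, species interactions, and non-ultrametric trees.
Passing tests therefore demonstrate that the *statistics and plumbing* are
correct and calibrated under known truth — not that any real flora has
been reanalysed.  Numbers computed on synthetic worlds (priority splits,
sympatry rates, Mantel correlations) are analogues, not reproductions, of
published values from real datasets.

## Numerical conventions

* Permutation p-values always use `(1 + #extreme) / (n_perm + 1)`.
* Ties: ROC threshold → lowest candidate; cluster majority → lowest
  cluster id; priority table → band, then FPS, then taxon name.
* Degenerate inputs fail loudly: empty ranges, zero-mass surfaces,
  zero-variance columns under standardisation (named in the error),
  misaligned grids, mismatched tip labels (offenders listed).
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the pipeline derives all internal seeds from the one
  configuration seed, which is why double runs are byte-identical.
* D, I and derived fractions are clamped against sub-1e−12 floating-point
  excursions outside [0, 1]; the FPS/band arithmetic is exact.
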