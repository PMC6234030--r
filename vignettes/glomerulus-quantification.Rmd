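---
title: "Quantifying a glomerular connectome: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a glomerular connectome: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomquant)
```

## The problem

Dense electron-microscopy reconstruction of an antennal-lobe glomerulus
yields three tables: identified neuron bodies (olfactory receptor neuron
axons arriving ipsilaterally or through the commissure, projection neurons,
local interneurons), presynaptic T-bar ribbons, and the postsynaptic
densities (PSDs) apposed to each T-bar. Insect synapses are *polyadic*: one
T-bar drives several PSDs at once, so "a synapse" and "a connection" are not
the same thing. glomquant turns such annotations into the quantitative
objects connectomic papers report — a cell-by-cell contact matrix, per-cell
synaptic statistics, class-level flow diagrams, reciprocity motifs, and
density-based spatial territories — and ships a calibrated synthetic
generator so that every stage can be verified against ground truth without
an EM volume.

## The counting model

The unit of counting is one **directed contact**: one PSD contributes one
contact from the T-bar's host cell to the PSD's host cell. A T-bar with
$k$ PSDs therefore contributes $k$ contacts ("triads" at $k=3$, "tetrads"
at $k=4$); the PSDs of one polyad are coordinately linked to a single
release site but are counted as separate pairwise contacts, which is the
convention behind deposited connectivity matrices. Consequences that the
test-suite invariants pin down:

* `expand_contacts()` emits exactly one contact per PSD, so the total
  contact count equals the PSD count.
* Autapses (pre body = post body, occasionally seen on PN axons) are
  flagged, retained, and land on the matrix diagonal.
* T-bars without any PSD are excluded from every count, matching the
  annotation practice of removing the small minority of T-bars that lack
  clear PSDs.
* Contacts to bodies missing from the cell table are kept and attributed to
  a reserved `orphan` class — orphan fragments with enough contacts appear
  in the matrix like any cell, which is how deposited matrices treat them.
* Conservation: matrix total + contacts touching excluded bodies = total
  PSD count, on every dataset.

**Inclusion filter.** The matrix covers bodies with *more than 50 contacts*
in the glomerulus. Published phrasings waver between a combined total and
"pre- or postsynaptic" counts, so the threshold is exposed:
`filter_included_bodies(totals, min_total = 51, count_mode = "total")`
implements the combined reading (the default); `count_mode = "either"`
requires one direction alone to reach the threshold.

**Per-cell statistics** mirror the columns of deposited per-cell tables:
T-bar count, contacts driven (`pre_contacts`) and received
(`post_contacts`), mean PSDs per T-bar, pre:post ratio, and T-bar density
per µm³ of intraglomerular neurite volume. Ratios with zero denominators
are flagged missing (`NA`), never infinite, so tables serialize cleanly;
display rounding is left to report formatting.

## Reciprocity

For every unordered pair the two directed strengths are read off the
matrix. A pair is **reciprocal** when both directions carry at least
`min_each = 3` contacts — three being the conventional floor below which a
"pathway" may be proof-reading noise. A reciprocal pair is **strong** when
its direction ratio falls in the configured band. Two readings of the
strong criterion circulate: highlighted ratios *between* 0.25 and 4
(`band_mode = "within"`, the default) versus *at least* a 4:1 imbalance
(`band_mode = "outside"`). Both are implemented; adjudicating which
reading reproduces the published strong-pair count requires the deposited
192-cell matrix, which cannot be redistributed here, so the default simply
follows the figure-legend reading. Percentages are reported against a
universe of pairs whose stronger direction reaches `min_each`; published
pair universes cannot be reconciled exactly with any single pairing rule,
so the universe definition is a parameter rather than a guess.

The exported ratio matrix reflects inversely about the diagonal (0.25 on
one side is 4 on the other), and the class-pair summary reports, per class
pair, the share of reciprocal pairs, the dominant pre-class with its share,
and the mean ratio oriented along that dominant direction.

## Class flows and ratio classification

`aggregate_by_class()` sums the matrix over class members and expresses
each directed class pathway as a percent of **all** contacts in the matrix
(the percentages over all class pairs sum to 100). That denominator choice
follows the arithmetic of published flow figures, where the per-target ORN
shares sum to the total ORN output share.

Cells separate cleanly by their pre:post ratio: sensory inputs are strongly
presynaptic (class ratios near 4–5), outputs predominantly postsynaptic
(0.06–0.4), local interneurons near parity. `classify_by_ratio()` encodes
this as an ordered rule list — ratio ≥ 2.5 → ORN, ratio ≤ 0.6 → PN,
otherwise LN — with closed boundaries on the ORN/PN side and a
`near_boundary` note within ±20% of a threshold, where assignment is least
certain. The thresholds are configuration, not biology: published sources
show the separability but print no decision rule, so the defaults are
placed between the printed class clusters and exposed as a rule table.

## Synapse point clouds and territory demarcation

Glomerular borders appear as local rarefactions in the synapse point
cloud. `density_map()` bins T-bar positions into cubic voxels (default
1 µm, i.e. 125 steps of the 8 nm imaging grid) on a half-open lattice and
smooths with a separable Gaussian (default σ = 2 voxels). The grid is
zero-padded beyond the point extent by the kernel radius, so raw counts
conserve the number of points and smoothing conserves total mass to
numerical precision; with the default auto-origin (coordinate minimum minus
the padding) the whole construction is translation-equivariant.

`segment_regions()` thresholds the smoothed density and labels 26-connected
components, discarding regions below `min_region_points` and numbering the
rest by descending point count (ties broken by first voxel index, so
labelling is deterministic). The default threshold is the 60th percentile
of smoothed density *over point-occupied voxels*. The quantile is taken
over occupied voxels rather than all nonzero smoothed voxels deliberately:
smoothing spreads vanishingly small densities over a halo whose size
depends on padding, and a quantile over that halo lands far below any
inter-glomerular saddle, merging territories that are plainly separate. The
occupied-voxel quantile is insensitive to padding and, in the calibration
scenarios (1–3 Gaussian territories, separations down to 6σ), recovers the
generating count exactly.

Two scoring notes. First, any quantile threshold keeps only the densest
~40–80% of points inside labelled voxels, so segmentation quality is scored
by **purity** — the fraction of a region's points that originate from the
generating territory nearest its centroid — rather than by recall, which no
thresholding method can push past the inter-territory saddle (~90% for two
3 µm territories 20 µm apart). Second, a watershed variant for *touching*
territories was considered and not implemented: no 3D watershed is
available in the package's dependency set, and the threshold/components
demarcation covers the separated-territory regime the generator produces.
This is a known limitation for abutting glomeruli.

## The synthetic generator

`synth_config()` fixes the study conditions; `generate_glomerulus()` draws
a dataset. Defaults, with the reasoning:

| parameter | default | rationale |
|---|---|---|
| census | 51 ipsi ORN, 56 contra ORN, 18 PN, 56 LN, 2 minor | the reconstructed census of a pheromone-responsive glomerulus |
| `total_tbars` | 11,144 | published presynaptic-site total |
| `psd_mean`, `psd_max` | 3.4 over 1..9 | printed polyad statistics; law is 1 + truncated Poisson, rate solved numerically at configuration time (`calibrate_polyad_lambda()`), never hard-coded |
| `flow_targets` | ORN 39.5/14.5/5.9; LN 10.4/7.8/9.6; PN 6.4/4.1/1.8 (% of all contacts) | published class-flow shares; propensity rows are these shares renormalized per pre-class |
| `orn_ipsi_output_share` | 0.7 | ipsilateral share of total ORN output |
| `receptivity` | ipsi ORN 3, others 1 | within-class target weights; the 3:1 ipsi bias keeps contralateral ORN pre:post ratios inside the ORN cluster, as measured per-cell tables show |
| `tail_alpha` | 0.15 | Dirichlet concentration of the partner urn; chosen so ~23% of possible ordered pairs are connected and ~37% of connected pairs carry ≥3 contacts |
| `tbar_nb_size` | 40 | negative-binomial dispersion of per-cell T-bar counts; tight enough that per-class ratio clusters stay separated |
| `autapse_rate` | 0.01 (PN only) | autapses are ~1% of a PN axon's synapses |
| `orphan_rate`, `n_orphans` | 0.03, 6 | a small unassigned fraction spread over six orphan fragments, which end up included in the matrix as in real reconstructions |
| `neuropile_volume_um3` | 4,858 | published neuropile volume; cell volumes are drawn to fill 87% of it |
| spatial | centres ≥ 6σ apart, σ = 3 µm, clouds of 50,000 points | well-separated Gaussian territories at desk scale |

Partner choice is a Dirichlet-multinomial urn per (presynaptic cell, target
class): a weight vector is drawn once from a Dirichlet with concentration
`tail_alpha` × receptivity and the cell's PSDs toward that class sample
i.i.d. from it. This is exactly the exchangeable form of preferential
attachment (a Pólya urn), so per-pair strengths come out heavy-tailed —
most connections carry few contacts, a minority carry many — with a single
interpretable knob. The draw order is fixed and documented in
`?generate_glomerulus`, so one seed reproduces a dataset bit-for-bit, and
the generator restores the caller's RNG state.

Calibration was verified by simulation before the test thresholds were
frozen: across 20 seeds at the default size, realized class-flow shares
stayed within 1 percentage point of the configured targets (tests assert
3), the empirical PSDs-per-T-bar mean stayed within 3.4 ± 0.06 (tests
assert ± 0.1), the ≥3-contact share of connected pairs stayed within 2
points of 37% (tests assert 3), and the ratio classifier recovered at least
92% of included ORN/PN/LN cells against generator truth (tests assert 90%).

**What the generator does and does not emulate.** It reproduces the census,
polyad-size law, class-level flow structure, heavy-tailed pair strengths,
laterality asymmetry, rare PN autapses, orphan fragments, and clustered
T-bar positions. It does **not** model neurite morphology, subtype-level
propensities (within-class targeting is uniform up to receptivity, so
subtype statistics such as the near-zero ratio of one multiglomerular PN
subtype are not reproduced), bilateral or inter-glomerular wiring,
synapse-size variation, or non-Gaussian territory shapes. Passing the
property suites therefore certifies the *bookkeeping* — expansion,
filtering, aggregation, reciprocity and segmentation are exact on data
whose ground truth is known — not that real glomeruli look like the
generator.

## Numerical conventions

* Coordinates are nanometres throughout; 8 nm/voxel conversion happens in
  `read_point_cloud()` only.
* Voxelization is half-open: a point on a bin boundary belongs to the upper
  bin.
* Undefined ratios (zero denominator) are `NA` everywhere, and excluded
  from ratio means.
* Matrix rows/columns default to the display convention: outputs (PNs)
  first, then interneurons (LNs), then inputs (ORNs), then minor classes
  and orphans, alphabetical by name within class.
* Dense CSV matrix output is byte-stable: fixed field order, `\n` line
  endings, no quoting — write/read/write produces an identical file.
* All readers reject malformed input with the offending line or cell named;
  there is no delimiter sniffing.

## Problem sizes used by the checks

The shipped test-suite and acceptance script run entirely on synthetic
data: full-size glomeruli (~11,000 T-bars, ~38,000 PSDs, 183 cells) for
calibration and recovery checks, 100 randomized small configurations
(150–500 T-bars) for conservation, 1,000 random matrices up to 20×20
against brute-force references, and 50,000-point clouds for segmentation.
These sizes were chosen so the whole suite completes in about half a minute
while keeping the Monte-Carlo intervals comfortably inside the asserted
tolerances. Checks that require the deposited 192-cell connectivity matrix
run automatically when that file is placed under `inst/extdata/` (see
`?read_matrix`); it is not redistributable with the package.
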