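# glomquant

Quantification of glomerular connectomes from polyadic synapse annotations.

Dense EM reconstruction of an olfactory glomerulus (e.g. an antennal-lobe
glomerulus in *Drosophila*) produces tables of identified neuron bodies,
presynaptic T-bar ribbons, and the postsynaptic densities (PSDs) apposed to
each T-bar. Because insect synapses are polyadic — one T-bar typically
faces three or four PSDs — turning these annotations into circuit numbers
requires a consistent counting model. glomquant implements that model and
every downstream statistic a connectomic study of a glomerulus reports:

* **Contact expansion** — each PSD becomes one directed contact
  (pre cell → post cell); a T-bar with *k* PSDs contributes *k* contacts;
  autapses are flagged and kept.
* **Contact matrix** — bodies with more than 50 contacts enter a
  cell-by-cell matrix `M`, where `M[i, j]` counts contacts from cell *i* to
  cell *j* (diagonal = autapses), ordered PN, LN, ORN by convention.
* **Per-cell statistics** — T-bars, contacts driven/received, PSDs per
  T-bar, pre:post ratio, T-bar density per µm³ of neurite volume.
* **Connectivity selectivity** — of the *n*² possible ordered pairs, how
  many are connected, how many at the ≥3-contact pathway criterion, how
  many above 10 contacts; the full connection-strength histogram.
* **Class flows** — the matrix aggregated by cell class, each directed
  class pathway as a percent of all contacts; GraphML/DOT/edge-list export.
* **Ratio classification** — cells assigned to ORN/LN/PN from their
  pre:post ratio (defaults: ≥ 2.5 → ORN, ≤ 0.6 → PN, between → LN).
* **Reciprocity** — pairs connected in both directions at ≥ 3 contacts
  each, direction ratios, the strong-reciprocity band (0.25–4), and
  class-pair summaries.
* **Point-cloud segmentation** — 3D synapse density maps (1 µm bins,
  Gaussian smoothing) segmented into glomerulus-like territories at local
  density rarefactions, for region-of-interest assignment.
* **Synthetic glomeruli** — a calibrated generator
  (census 51 + 56 ORNs, 18 PNs, 56 LNs; 11,144 T-bars; 3.4 PSDs/T-bar;
  published class-flow shares; heavy-tailed pair strengths) with ground
  truth for every stage.

See `vignette("glomerulus-quantification")` for the models, parameter
rationale and design choices.

## Worked example

```r
library(glomquant)

g <- generate_glomerulus(synth_config(seed = 7))
d <- g$dataset
d
#> <glomerulus_dataset>
#>   cells: 183   T-bars: 11508   PSDs: 38906
#>   neuropile volume: 4858.0 um^3

contacts <- expand_contacts(d)          # one directed contact per PSD
totals   <- cell_contact_totals(contacts)
included <- filter_included_bodies(totals)   # > 50 contacts
mat      <- build_contact_matrix(contacts, included, d$cells)

connectivity_summary(mat)[c("possible_pairs", "connected_pairs",
                            "pct_connected", "pct_ge3_of_connected")]
#> $possible_pairs        34969
#> $connected_pairs        8127
#> $pct_connected          23.2
#> $pct_ge3_of_connected   36.6
```

23% of the possible ordered cell pairings actually make contact, and 37% of
the connected pairs reach the three-contact pathway criterion — the
selectivity signature of a real glomerulus. The class-level flows recover
the generator's configured calibration (ORN output dominates, mostly onto
PNs):

```r
head(aggregate_by_class(mat, d$cells)$flows, 5)
#>   pre_class post_class contacts percent_of_total
#> 1       ORN         PN    15117            38.86
#> 2       ORN         LN     5468            14.05
#> 3        LN         PN     3610             9.28
#> 4        LN         LN     3498             8.99
#> 5        LN        ORN     2732             7.02

class_stat_summary(per_cell_stats(d, contacts), "pre_post_ratio")
#>        group  n  mean     sd
#> 1         LN 56 0.941 0.3006
#> 2 ORN_contra 56 4.528 1.5532
#> 3   ORN_ipsi 51 4.169 0.9241
#> 4     orphan  6 0.000 0.0000
#> 5      other  0   NaN     NA
#> 6         PN 18 0.264 0.0867
```

The per-class pre:post ratio clusters (ORNs strongly presynaptic, LNs near
parity, PNs postsynaptic) are what `classify_by_ratio()` exploits to
recover cell classes from connectivity alone. Reciprocity, read off the
same matrix:

```r
ra <- reciprocity_analysis(pair_table(mat))
ra$summary[c("n_universe", "n_reciprocal", "n_strong")]
#> $n_universe    2789
#> $n_reciprocal   175
#> $n_strong       143
```

Real annotation tables enter through `read_synapse_table()` (TSV/JSON, one
record per PSD), `read_cell_table()` (CSV), and `read_matrix()` (dense
CSV/XLSX grid or edge list); a thin command-line front end over the same
functions ships at `inst/cli/glomquant.R`.

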