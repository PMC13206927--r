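# ibrtox

Network-toxicology studies ask two computational questions on the way
from a candidate toxicant (or a protective compound) to a mechanism: do
the compound's predicted targets overlap a disease gene set more than
chance, and — once the cell biology has been measured — how much overall
damage did each treatment group sustain across a battery of biomarkers?
`ibrtox` implements that computational arc for R users: gene-list
intersection with hypergeometric overlap significance, a local
over-representation analysis (ORA) against GMT annotations with
Benjamini–Hochberg FDR, 2^−ΔΔCt relative quantification, and the
Integrated Biomarker Response (IBR) index that condenses a multi-group
biomarker panel into one damage score per group. A seeded synthetic-data
generator produces every input format the pipeline reads, so the whole
flow is testable offline.

## The IBR index

For group means `X[g, b]` (groups × biomarkers):

1. `Y = (X - m_b) / s_b` — standardize each biomarker across groups
   (sample SD by default; `sd_mode = "population"` available).
2. `Z = ±Y` — sign per biomarker so larger `Z` always means a larger
   treatment response (`+` for up-regulated, `−` for down-regulated
   biomarkers).
3. `S = Z + |min(Z)|` — translate per biomarker so the least-responding
   group sits at radius 0.
4. `IBR = Σ S_i S_{i+1} sin(2π/k) / 2` (wraparound) — the area of the
   radar polygon with the `k` biomarkers on equally spaced axes.

Higher index = greater overall toxicological impact. The index depends
on the biomarker axis order; `order_sensitivity()` reports the spread
over orderings instead of hiding it.

## Worked example

```r
library(ibrtox)

ws <- tempfile("demo")
write_fixtures(ws, seed = 1)            # gene lists, GMT, panel, config
run_pipeline(file.path(ws, "config.yaml"))
```

The pipeline logs each stage and writes `overlap.tsv`,
`enrichment.tsv`, `ibr_scores.tsv`, `ibr_index.json`, `radar.svg` and a
checksummed `manifest.json` under the configured output directory.
Running the same flow step by step (the `analysis/` scripts do exactly
this) prints, for the default three-arm panel:

```
radar radii (S):
          PINK1  PRKN  LC3B TOM20 CASP3   AIF   ATP   MMP
control   0.000 0.000 0.000 0.000 0.000 0.000 0.000 0.000
toxicant  1.994 1.997 1.954 1.977 1.992 1.982 1.994 1.974
protected 1.133 0.903 0.608 0.726 1.152 1.222 0.861 1.264

IBR index per group:
  control  toxicant protected
    0.000    11.122     2.767
```

The control group defines the least-responding profile on every axis
(radius 0, index 0); the full-dose toxicant arm encloses the largest
polygon; the pretreatment arm lands in between — the protective-effect
signature the index is designed to display. The overlap stage on the
same workspace reports a 21-gene intersection between the 164-gene
compound-target list and the 865-gene disease list (p = 8.5e-06 against
a 20000-gene background), and the enrichment stage ranks the planted
annotation term first at q = 1.3e-06 with no background term below
q = 0.05.

## The analysis scripts

`analysis/01_simulate.R` … `05_sensitivity.R` run the study end to end:
simulate the workspace, intersect the gene lists, run ORA, compute the
IBR with its radar chart, and probe robustness (axis-order spread,
ordering stability across 100 regenerated panels). Each writes its
tables under `results/`.

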