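---
title: "Quantifying overall toxicological impact: gene-set overlap, enrichment, and the IBR index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying overall toxicological impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibrtox)
```

## The problem

Network-toxicology studies of a candidate toxicant (and, symmetrically,
network-pharmacology studies of a protective compound) follow a common
computational arc: predicted compound-target gene lists are intersected
with disease gene lists, the shared targets are characterized by
over-representation analysis against functional annotations, and the
downstream cell-biology readouts — a battery of biomarkers spanning, for
example, mitophagy, mitochondrial metabolism and apoptosis — are
condensed into a single per-group index of overall damage. `ibrtox`
implements that arc as a reusable, fully seeded pipeline. The motivating
setting is a three-arm in vitro design: an untreated control, a
toxicant arm, and a pretreatment arm in which a candidate protective
compound is given before the toxicant.

## The IBR index

The core statistic is the Integrated Biomarker Response (IBR), a
radar-plot area index over a biomarker battery. Let `X[g, b]` be the
mean value of biomarker `b` in treatment group `g` (arbitrary assay
units: fold changes, activities, intensities). The construction is:

1. **Standardize** per biomarker across groups:
   `Y[g, b] = (X[g, b] - m_b) / s_b`, where `m_b` and `s_b` are the mean
   and standard deviation of column `b` over the groups. This removes
   units, so biomarkers measured on wildly different scales contribute
   comparably (and makes the whole chain invariant to positive affine
   rescaling of any biomarker — a property the test suite checks).
2. **Sign by direction**: `Z = +Y` for biomarkers that respond upward
   upon treatment, `Z = -Y` for those that respond downward. After this
   step, larger `Z` always means "more response".
3. **Translate**: `S = Z + |min(Z)|`, the minimum taken per biomarker
   across groups, so every score is non-negative and, per biomarker, the
   least-responding group sits at radius zero.
4. **Area**: place the `k` biomarkers on equally spaced radar axes
   (axis `i` at angle `2*pi*(i-1)/k`) with radius `S`, and take the area
   of the closed polygon,
   `sum_i S_i * S_{i+1} * sin(2*pi/k) / 2` with wraparound. That
   adjacent-spoke triangle sum equals the shoelace area of the polygon
   for equally spaced axes.

A higher index means a larger overall departure from the
least-responding profile — for a toxicant battery, more severe damage.

### Choices the construction leaves open

The IBR recipe as usually stated underdetermines several details; each
is an explicit argument here rather than a silent assumption.

* **SD flavor** (`sd_mode`): sample SD (`n - 1`, the default, the common
  choice in the IBR literature) or population SD. With only a handful of
  groups the choice rescales every `Y`, so it must be explicit. A
  useful closed form for sanity checks: with exactly two groups and
  sample SD, every non-constant biomarker gives `|Y| = sqrt(2)/2`.
* **Scope of `min(Z)`** (`min_scope`): per biomarker (default, following
  the original IBR construction) or global over the whole matrix. Under
  the per-biomarker scope, centering guarantees `min(Z) <= 0`, so the
  minimizing group really does land at radius 0. `|min(Z)|` is added
  literally even if the minimum is positive (only reachable under the
  global scope).
* **Axis order**: the index depends on which biomarkers share adjacent
  axes. The package keeps the caller's input order and surfaces the
  dependence through `order_sensitivity()`, which enumerates all
  circular orderings (up to rotation and reflection) when `k <= 6` and
  samples orderings otherwise. At `k = 3` the index is
  ordering-invariant; at `k = 4` there are at most three distinct
  values.
* **Constant biomarkers** (`s_b = 0`): standardized to 0 with a warning
  instead of failing, so a panel with one flat readout stays computable.
* **Degenerate geometry**: at `k = 2` the two axes are antiparallel and
  the polygon has zero area whatever the scores; the index is only
  informative from `k = 3` up.
* **Directions**: caller-supplied flags are the default; `infer_directions()`
  can derive them from the sign of (treated mean − control mean) given a
  designated control group, and reports what it inferred. The math never
  privileges the control label otherwise.

No inference is attached to index differences: the package reports the
per-group areas and their ordering-robustness, not p-values; bootstrap
intervals over replicates are deliberately out of scope.

## Gene-set overlap and enrichment

`normalize_symbols()` does uppercase-and-trim normalization only — no
alias or identifier mapping, which would require an external database.
`overlap_significance()` asks whether two lists share more genes than a
hypergeometric draw from an explicit background universe would give
(one-sided, excess overlap only). The universe size is a required
argument: published intersections routinely omit their background, and
defaulting one would manufacture significance out of thin air.

`run_ora()` is a local, self-contained over-representation analysis:
exact hypergeometric upper-tail p-values per GMT term, with
Benjamini–Hochberg adjustment across all terms of the collection (the
field-default multiple-testing procedure), ranking ties broken
lexicographically by term id so output is deterministic. Query genes
absent from the universe are dropped but reported as a coverage
fraction, mirroring how enrichment services treat unmapped symbols while
keeping the discrepancy visible. GO-graph propagation, term redundancy
trimming and ranked-list (GSEA-style) methods are out of scope.

`ddct_fold_change()` provides the standard 2^−ΔΔCt relative
quantification used to turn qPCR Ct values into the fold changes that
feed a biomarker panel.

## What the synthetic generator emulates

`generate_panel()` emulates the replicate structure of a three-arm
cytotoxicity study: each replicate is
`baseline * (1 ± delta * multiplier) + N(0, noise_sd)`, with the sign
set by the biomarker's direction and the multiplier by the arm (0 =
control, 1 = full toxicant effect, 0.5 = pretreatment at half effect).
The defaults — eight biomarkers covering mitophagy markers suppressed by
the toxicant (PINK1, PRKN, LC3B, TOM20), apoptosis markers induced
(CASP3, AIF) and metabolic readouts suppressed (ATP, MMP); baseline 1;
relative effect `delta = 0.4`; `noise_sd = 0.1` (a 10% CV, typical of
normalized qPCR/assay data); four replicates per cell — describe a
clear-but-noisy effect of the size such panels are run to detect.
Gaussian noise matches the mean ± SEM reporting convention of such
assays and keeps closed-form expectations for the convergence tests.
The generator is multiplicative-only (no additive effect option) so
directions and effect sizes compose simply.

`generate_overlap_sets()` plants an exact intersection between two gene
lists; the default shape (164- and 865-gene lists sharing 21 genes) is
the size signature of a typical compound-target versus disease-gene
comparison, placed in a 20000-gene universe — roughly the protein-coding
gene count, and the smallest natural background for target lists (two
such lists cannot even coexist in a universe much below ~1000 without
being forced to overlap).

`generate_annotation()` builds GMT annotations: by default a 1000-gene
universe, a 100-gene query, 200 background terms of 20–200 genes drawn
uniformly, and one planted term of 50 genes sharing exactly 20 with the
query (expected overlap under the null: 5). The background sizes were
chosen so that the discreteness of the hypergeometric does not make the
nominal 0.05 level grossly conservative: with these sizes the attained
per-term type-I rate is about 0.035, computed directly from the
hypergeometric mass function, and the simulation tests check the pooled
empirical rate against that band. All generators are pure functions of
their spec, seed included: identical specs give identical bytes.

**What passing on synthetic data does not show**: real panels have
correlated biomarkers, non-Gaussian and heteroscedastic noise, and
batch structure; real annotations have overlapping, nested terms and
incomplete universes. The synthetic tests establish that the machinery
computes the defined quantities correctly and recovers planted signals
of realistic size — not that the defaults match any particular assay's
error model.

## Pipeline and determinism

`run_pipeline()` executes the stages in the fixed order overlap →
enrich → ibr from a YAML config, validating every referenced path and
option before any stage runs. The enrichment query defaults to the
overlap stage's intersection (the usual flow: enrich the shared
targets) unless an explicit query list is configured. Every output is
listed in a manifest with an md5 checksum; identical config and inputs
reproduce byte-identical outputs, which is what the determinism tests
assert. The radar chart is emitted as SVG by a small deterministic
writer (fixed numeric formatting), with one polygon per group and a
dashed reference polygon marking the locus where the signed score `Z`
is zero on every axis — the baseline for the standardized values.

## A worked run

```{r demo, eval = FALSE}
ws <- tempfile("demo")
write_fixtures(ws, seed = 1)
manifest <- run_pipeline(file.path(ws, "config.yaml"))
jsonlite::read_json(file.path(ws, "results", "ibr_index.json"))
```

The `analysis/` scripts in the source repository run the same flow as a
narrated five-step study (simulate, overlap, enrichment, IBR,
sensitivity) and write their tables under `results/`.

## Problem sizes used in the test suite

The simulation-based checks run at sizes chosen to estimate the rates
they assert with comfortable margins: 50 random panels (2–6 groups ×
2–8 biomarkers) against the step-by-step oracle; exhaustive
hypergeometric enumeration for every feasible configuration with a
universe of at most 12; type-I calibration pooled over 20 × 1000 null
terms; planted-term recovery and toxicity-ordering rates over 100
seeds each.

## Limitations

* The index is descriptive: two groups can differ in index while
  overlapping heavily at the replicate level, and no test of index
  differences is provided.
* Axis-order dependence is bounded empirically, not removed; reporting
  the `order_sensitivity()` spread alongside the index is recommended.
* Symbol handling is string-normalization only; lists mixing symbol
  conventions (aliases, Ensembl ids) will under-intersect.
* ORA treats terms independently; strongly overlapping annotation terms
  will co-rank, as in any unpruned enrichment.
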