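---
title: "Same-cell metabolome and transcriptome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Same-cell metabolome and transcriptome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scduet)
options(scduet.verbose = FALSE)
```

## The measurement design

scduet analyzes plate-based experiments in which single plant protoplasts are
dispensed into wells, lysed, and the lysate is split in half: one half goes
to targeted LC-MS metabolomics, the other to plate-based scRNA-seq. Because
both halves come from the same physical cell, the two modalities can be
joined exactly by well identity — no computational alignment, label transfer
or mutual-nearest-neighbour matching is needed, and the package deliberately
offers none. Every join in the package is keyed on the well ID string.

The pipeline stages are:

1. **Quantify** (`calibrate()`, `quantify_wells()`): peak areas to absolute
   intracellular concentrations.
2. **QC and normalize RNA** (`qc_filter()`, `normalize_expression()`).
3. **Integrate** (`join_by_well()`, `normalize_metabolites()`).
4. **Annotate** (`annotate_cells()`, `cross_tabulate()`): marker-rule labels
   from each modality, compared.
5. **Correlate** (`spearman_matrix()`, `loess_trend()`,
   `build_transporter_network()`, `wilcoxon_de()`).

## Absolute quantification model

Each analyte's response is modelled as linear in the analysis-solution
concentration: `area = slope * conc + intercept`. `fit_calibration()` fits
ordinary least squares of the *mean* replicate area on the nominal
concentration of each standard. Standards whose mean area is zero sit below
the instrument's detection floor and carry no signal; they are excluded from
the line fit (keeping them would bias the intercept by the full magnitude of
the censored response) but retained in the series, where they fail the LOQ
accuracy check below.

The limit of quantification follows the common accuracy-and-precision rule:
the LOQ is the lowest standard whose back-calculated mean concentration is
within ±20% of nominal and whose replicate CV is at most 20%
(`determine_loq()`, both tolerances configurable). Back-calculated sample
concentrations below the LOQ are censored to 0 and flagged, so a reported
nonzero concentration is always a quantified one.

For a single cell, `quantify_cell()` inverts the measurement chain:

* analysis concentration: `(area - intercept) / slope`, clamped at 0;
* amount in the measured aliquot: `conc_uM * aliquot_volume_uL * 1000` fmol
  (1 µM x 1 µL = 1 pmol); `aliquot_volume_uL` defaults to 4, the injected
  analysis volume;
* whole-cell amount: multiplied by `split_factor = 2`, because only half of
  the lysate was analyzed;
* intracellular concentration: the amount divided by the spherical cell
  volume `V = (pi/6) d^3`, with the diameter `d` in µm measured from the
  picking images, so `V` is in µm³ = fL and fmol/fL = mol/L.

No shape correction is applied to the sphere, and calibration is purely
external — no internal-standard normalization enters the single-cell
concentrations. Wells with no cell are back-calculated the same way by
`background_report()` to check for leakage of metabolites into the medium.

## RNA processing

Cells are kept when they come from single-cell wells and detect strictly
more than 1,000 and strictly fewer than 10,000 genes, where "detected"
means a raw count above zero (the minimal reading of detection; the bounds
are exclusive on both sides). TPM uses the standard length-normalized form
with lengths from the input sidecar; log-normalization is
`ln(1 + 1e4 * count / total)`. Variable genes are selected by the
variance-stabilizing rule: a LOESS fit (span 0.3) of log10 variance on
log10 mean across genes, counts standardized by the fitted sd and clipped at
`sqrt(n_cells)`, genes ranked by the variance of the standardized values;
ties break by gene ID so that the selection is a pure function of its input.

## Integration and dual annotation

Metabolite concentrations are transformed as `log10(1 + conc)` — a 1 µM
pseudocount keeps absent analytes at exactly 0 and the transform monotone —
and then standardized per analyte *within each collection batch* (sample sd,
n−1; a two-point batch therefore gets z = ±1/sqrt(2)). The batch-z layer of
the quantified analytes is the feature space for the metabolite embedding;
the scaled variable-gene layer drives the RNA embedding. UMAP (via uwot,
fixed seed, `n_neighbors = 15`, `min_dist = 0.1`) is the default view; a
deterministic PCA fallback with a fixed sign convention is provided because
exact UMAP coordinates depend on library internals, and strict
reproducibility tests should not.

Annotation is rule-based, not cluster-based. RNA rules fire on marker
detectability (count ≥ 1): D4H/DAT → idioblast, G8H/ISY → IPAP, NLTP2 →
epidermis, in that priority order; idioblast markers outrank the others
because they are the most cell-type-exclusive, and conflicts are logged.
Metabolite rules fire on presence above the LOQ: serpentine → idioblast,
loganic acid → loganic-acid cell, secologanin with mauritianin → the
mauritianin epidermal subtype, secologanin alone → epidermis. Presence was
deliberately tied to the LOQ rather than to any nonzero signal, so that the
annotation inherits the quantification's censoring guarantees. Cells
matching no rule stay `unassigned` rather than being called parenchyma by
exclusion. `cross_tabulate()` counts cells per label pair (the Sankey view),
and `co_annotation_fraction()` reports count-based percentages rounded
half-up to integers.

## Correlation analysis

`spearman_matrix()` correlates each gene's TPM with each analyte's
concentration using midranks. By default all jointly profiled cells enter,
with below-LOQ concentrations as 0: the presence/absence contrast between
cell types is part of the biological signal, and discarding the zeros would
erase it. A `cells = "detected"` mode restricts each analyte to its
quantified cells for sensitivity analysis. Constant vectors yield `NA`, and
per-analyte ranks (1 = most positive) cover the non-NA genes.

`loess_trend()` fits a local linear regression (tricube weights, degree 1)
of expression on concentration with a pointwise 95% band (fit ± 1.96 SE).
The default span is 0.75, appropriate for a smooth overview trend; for
localizing the maximum of a peaked dose-expression curve a smaller span
(0.4 in the package's own checks) reduces smoothing bias at the mode, which
a degree-1 local fit otherwise flattens.

`build_transporter_network()` links each analyte to its 15 most positively
and 15 most negatively correlated transporters (both configurable), skipping
NA correlations and breaking ties at the cutoff by gene ID, with a log
message, since a silent tie-break would make the network irreproducible.
Exports go to SIF and GraphML via igraph, with rho on edges and degree on
nodes.

`wilcoxon_de()` compares two disjoint cell groups per gene. With at most 10
cells in each group the two-sided p-value is computed by full enumeration of
all assignments of the pooled midranks (the probability of a rank-sum at
least as far from its null mean as observed), which remains exact under
ties; larger groups use the normal approximation with continuity and tie
correction. Multiplicity is handled by Benjamini-Hochberg; the log2 fold
change uses de-logged group means with a pseudocount of 1 to avoid division
by zero.

## The synthetic-plate generator

Because real same-cell datasets require a picking robot and a mass
spectrometer, the package ships a fully specified generator
(`simulate_experiment()`) whose defaults emulate the plate design it was
built for: four 96-well plates collected in two batches, about 24% empty
wells and 3% doublets, protoplast diameters uniform in 20-60 µm, and five
cell types — two epidermal subtypes (34% + 22%), idioblasts (8%), IPAP at
3% (held under the 4% share reported for this rare type), and parenchyma.
The analyte panel (`default_analytes()`) spans low-µM to tens-of-mM pools:
idioblast alkaloids, an epidermal seco-iridoid, a flavonoid restricted to
one epidermal subtype, and two *transported* compounds whose biosynthesis
genes are expressed away from the accumulating cells.

Counts are negative binomial with a shared size parameter (default 2;
`Inf` gives Poisson) around cell-type-structured means, scaled by a
log-normal library factor: markers are zero outside their type,
type-enriched background genes are elevated 12-fold, and the biosynthesis
genes of in-situ analytes follow the unimodal link
`g(c) = a log10(1 + c/c0) exp(-c/c1)` of their product's concentration in
the same cell — expression rises with the pool, peaks (at roughly 100 mM for
the default idioblast-alkaloid scales), then declines slightly, a
storage-phase pattern. Doublet wells are element-wise sums of two
independent component draws; empty wells are all-zero. Gene lengths and
baseline expression are treated as annotation: fixed for the gene universe,
not redrawn per seed, so independent simulated experiments share an
expression landscape and pseudobulk-vs-bulk comparisons are meaningful.

Transported analytes are the generator's most deliberate design point. A
compound whose source cells are *abundant* would show a strong negative
rank correlation with its biosynthesis genes (with a 60% source and an 8%
sink the phi coefficient is about −0.36), which is not the decoupling the
design intends to emulate: the emulated situation is a rare or sparse
source — a rare cell type (3% IPAP for the loganic-acid analog) or
expression in a small fraction (15%) of source cells (the catharanthine
analog) — under which the correlation is near zero.

Peak areas apply the forward model that quantification must invert — amount
= conc x sphere volume, halved, diluted into the aliquot — with proportional
noise (default CV 5%), an additive floor, and an instrument floor below
which the area records 0. Calibration ladders are positioned per analyte as
multiples (10^−2.5 to 10^1.5) of its expected median analysis concentration,
the way an analyst brackets expected sample levels; a single absolute ladder
across a panel spanning four orders of magnitude would leave unweighted OLS
accurate only near its top. Empty wells show traces of the four most
abundant analytes at a 5% rate, at half the median expected cell signal —
small against real cells but above the LOQ, so they register as the
occasional detections the background check looks for.

All draws derive from one integer seed with fixed per-stage offsets, so an
identical configuration reproduces bit-identical plates.

## What the synthetic data does and does not show

The generator reproduces the *structure* the pipeline exploits: cell-type
specificity, metabolite-gene coupling and its loss under transport, plate
layout, censoring, calibration chemistry, batch scale offsets. It does not
emulate ambient RNA, chimeric doublet profiles, retention-time drift,
matrix effects in ionization, or gene-gene correlation beyond cell-type
structure. Passing tests therefore demonstrate that the implementation is
faithful to its models and invertible where it should be — not that those
models capture every failure mode of real plates.

## Numerical choices and scale of the built-in checks

The package's own test suite and acceptance script run at the study's scale
(4 x 96 wells, 2,000 genes, 12 analytes) with 5-20 seeds per property; the
count-based percentages (89%, 76%, 66%) are checked by constructing datasets
with exactly those counts and running the same functions. The trend-peak
check asserts localization within ±0.25 log10 units (a quarter decade) of
the true argmax — peak position is compared on the log-concentration axis
because concentrations span decades. Round-trip I/O is asserted to 1e-9
relative tolerance; the noiseless quantify-simulate inversion to 1e-6
relative (observed ~1e-13). Degenerate inputs (all-zero cells, constant
features, single-cell batches, empty transporter lists) warn or error
explicitly rather than propagating NaN.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1L)
sim <- simulate_experiment(cfg)

cal <- calibrate(sim$standards)
met <- assemble_metabolite_matrix(
  quantify_wells(sim$peak_areas, cal, sim$wells), sim$wells)

qc <- qc_filter(sim$expr, sim$wells)
ds <- join_by_well(normalize_expression(qc$expr),
                   normalize_metabolites(met), sim$wells)

ann <- annotate_cells(ds, method = "pca")
cross_tabulate(ann)$table

ct <- spearman_matrix(ds$expr$layers$tpm, ds$met$conc_uM)
plot_rank_curve(ct, "vindoline", c("NMT", "D4H", "DAT"))
```

## Known limitations

* Doublet metabolite pools describe only the first component; doublets are
  excluded by QC before any downstream stage, so this shortcut is invisible
  to the pipeline, but the raw simulated areas of doublet wells should not
  be interpreted quantitatively.
* The unimodal concentration-expression link is a phenomenological shape,
  not a kinetic model; only its peak location and monotone flanks are
  asserted.
* Unweighted OLS calibration is accurate only within about two decades of
  the top of a ladder with proportional noise; the per-analyte ladder
  placement works around this, and a weighted fit would be the natural
  extension.
* Annotation rules are first-match-wins; a cell genuinely co-expressing two
  types' markers is resolved by priority, which is logged but not modelled.
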