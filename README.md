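# scduet

Same-cell transcriptome **and** metabolome analysis for plate-based
single-cell experiments on plant protoplasts.

## The problem

In plate-based same-cell multi-omics, each protoplast is dispensed into a
well, lysed, and the lysate is split in half: one half is measured by
targeted LC-MS, the other by plate-based scRNA-seq. Both modalities describe
the *same physical cell*, joined exactly by well identity. This design makes
questions answerable that dissociated single-modality atlases cannot touch:
which cells actually *store* a metabolite (as an absolute intracellular
concentration), whether those are the cells that *synthesize* it (or whether
the compound was transported in from elsewhere), and how biosynthetic gene
expression responds quantitatively to the size of the product pool.

scduet is the analysis side of that design, for bench scientists and
computational biologists working on specialized metabolism (the default
configuration is shaped like a monoterpene-indole-alkaloid leaf system with
epidermis, rare idioblasts, and rarer IPAP cells). It provides:

* **Absolute targeted quantification** — per-analyte external calibration
  curves (OLS of mean replicate area on nominal concentration), an
  accuracy/precision limit of quantification (±20% accuracy, CV ≤ 20%),
  censoring below LOQ, and conversion of a peak area to an intracellular
  concentration via the split-lysate doubling and the spherical cell volume
  `V = (π/6)·d³` (µm³ ≡ fL, so fmol/fL = mol/L):

  `conc_uM = 2 × (area − intercept)/slope × aliquot_µL × 10³ fmol / V_fL × 10⁶`

* **scRNA-seq QC and normalization** — single-cell wells detecting >1,000
  and <10,000 genes; TPM; `ln(1 + 10⁴·count/total)`; variance-stabilized
  variable-gene selection.
* **Integration and dual annotation** — well-identity join, per-batch
  z-scoring of `log10(1+conc)`, UMAP/PCA embeddings, marker-rule labels from
  each modality (RNA: D4H/DAT → idioblast, G8H/ISY → IPAP, NLTP2 →
  epidermis; metabolites: serpentine, loganic acid, secologanin ±
  mauritianin), and their cross-tabulation.
* **Gene-metabolite statistics** — Spearman correlation screens with rank
  curves, LOESS concentration-expression trends with 95% bands,
  top-15/bottom-15 transporter-metabolite networks (SIF/GraphML), and
  Wilcoxon rank-sum subcluster differential expression (exact by full
  enumeration for groups of ≤10 cells, ties included).
* **A ground-truth plate simulator** — four 96-well plates, two batches,
  empty wells and doublets, five cell types with known metabolite pools and
  biosynthesis genes (including *transported* analytes decoupled from their
  source genes), negative-binomial counts, and forward-modelled calibration
  standards and peak areas, so every stage is testable without any external
  download.

## Worked example

```r
library(scduet)

cfg <- sim_config(seed = 1L)          # 4 x 96 wells, 2,000 genes, 12 analytes
sim <- simulate_experiment(cfg)

cal <- calibrate(sim$standards)       # slope, r2, LOQ per analyte
met <- assemble_metabolite_matrix(
  quantify_wells(sim$peak_areas, cal, sim$wells), sim$wells)
met
#> <metabolite_matrix> 12 analytes x 289 cells; 88.8% below LOQ; batches: day1, day2

qc <- qc_filter(sim$expr, sim$wells)  # kept 253 of 384 wells
ds <- join_by_well(normalize_expression(qc$expr),
                   normalize_metabolites(met), sim$wells)
ds
#> <multiomic_dataset> 253 cells; 2000 genes; 12 analytes

ann <- annotate_cells(ds, method = "pca")
table(ann$rna_label, ann$met_label)["idioblast", "idioblast"]
#> 22      # every serpentine-accumulating cell carries the idioblast markers

ct <- spearman_matrix(ds$expr$layers$tpm, ds$met$conc_uM)
dplyr::filter(ct, analyte == "vindoline", gene %in% c("NMT", "D4H", "DAT"))
#>   gene  analyte     rho n_cells  rank
#> 1 D4H   vindoline 0.996     253     3
#> 2 DAT   vindoline 0.997     253     2
#> 3 NMT   vindoline 0.998     253     1
```

The three vindoline biosynthesis genes rank 1-3 of 2,000 by correlation with
their product — the in-situ signature — while the transported analytes'
biosynthesis genes stay near zero correlation with the pools they produce.
Most entries of the metabolite matrix are 0/below-LOQ because each compound
is confined to its accumulating cell type; that sparsity *is* the
presence/absence signal the annotation rules and correlations use.

`plot_rank_curve()`, `autoplot()` on trend curves, `plot_embedding()`,
`plot_cross_tabulation()` and `plot_transporter_network()` give ggplot views
of each result; `tidy()`/`glance()` methods cover calibration and DE tables.
See the vignette (`vignettes/same-cell-multiomics.Rmd`) for the models,
parameter meanings and design decisions.

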