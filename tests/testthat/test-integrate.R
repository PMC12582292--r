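test_that("well-identity join intersects modalities and reports drops", {
  wells <- make_wells(5)
  genes <- c("D4H", "DAT", "G8H", "ISY", "NLTP2")
  counts <- matrix(1L, 5, 4, dimnames = list(genes, wells$well_id[1:4]))
  es <- expression_set(counts, stats::setNames(rep(1000, 5), genes))
  conc <- matrix(1, 2, 4, dimnames = list(c("serpentine", "secologanin"),
                                          wells$well_id[2:5]))
  met <- metabolite_matrix(conc, matrix(FALSE, 2, 4))
  ds <- join_by_well(es, met, wells)
  expect_equal(ds$cells, wells$well_id[2:4])
  expect_setequal(ds$drop_report$well_id, wells$well_id[c(1, 5)])
  expect_equal(sort(unique(ds$drop_report$modality)),
               c("expression_only", "metabolite_only"))

  # symmetric: the shared cell set does not depend on sides
  expect_setequal(ds$cells, intersect(colnames(conc), colnames(counts)))

  met_none <- metabolite_matrix(
    matrix(1, 1, 1, dimnames = list("serpentine", "Z9")))
  expect_error(join_by_well(es, met_none, wells), "no shared cells")
})

test_that("a full-overlap join keeps every cell with an empty drop report", {
  wells <- make_wells(193)
  genes <- c("D4H", "NLTP2")
  counts <- matrix(1L, 2, 193, dimnames = list(genes, wells$well_id))
  es <- expression_set(counts, stats::setNames(c(1000, 1000), genes))
  met <- metabolite_matrix(
    matrix(1, 1, 193, dimnames = list("serpentine", wells$well_id)))
  ds <- join_by_well(es, met, wells)
  expect_length(ds$cells, 193)
  expect_equal(nrow(ds$drop_report), 0)
})

test_that("metabolite normalization: log pseudocount and per-batch z-scores", {
  conc <- matrix(c(0, 99, 999, 42), 1, 4,
                 dimnames = list("a", sprintf("c%d", 1:4)))
  met <- metabolite_matrix(conc, batch = c(c1 = "b0", c2 = "b1", c3 = "b1",
                                           c4 = "b0"))
  norm <- suppressWarnings(normalize_metabolites(met))
  expect_equal(norm$layers$log10["a", "c1"], 0)
  # two-point batch: z = +/- 1/sqrt(2) under the n-1 convention
  expect_equal(unname(norm$layers$batch_z["a", c("c2", "c3")]),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # permuting cells within a batch permutes z identically
  met_p <- metabolite_matrix(conc[, c(3, 2, 1, 4), drop = FALSE],
                             batch = c(c3 = "b1", c2 = "b1", c1 = "b0",
                                       c4 = "b0"))
  norm_p <- suppressWarnings(normalize_metabolites(met_p))
  expect_equal(norm_p$layers$batch_z[, c("c1", "c2", "c3", "c4"),
                                     drop = FALSE],
               norm$layers$batch_z)

  # constant analyte within a batch -> z = 0; single-cell batch warns
  conc2 <- matrix(c(7, 7, 3), 1, 3, dimnames = list("a", sprintf("d%d", 1:3)))
  met2 <- metabolite_matrix(conc2, batch = c(d1 = "bA", d2 = "bA",
                                             d3 = "bB"))
  expect_warning(norm2 <- normalize_metabolites(met2), "single cell")
  expect_true(all(norm2$layers$batch_z["a", c("d1", "d2")] == 0))
  expect_equal(norm2$layers$batch_z["a", "d3"], 0)
})

test_that("embeddings are deterministic and separate designed types", {
  sim <- joined_sim(small_cfg(seed = 40L))
  feats <- sim$ds$met$layers$batch_z
  xy1 <- embed_cells(feats, "umap", seed = 3L)
  xy2 <- embed_cells(feats, "umap", seed = 3L)
  expect_identical(xy1, xy2)
  expect_true(all(is.finite(c(xy1$dim1, xy1$dim2))))
  expect_error(embed_cells(feats[, 1:5], "umap", n_neighbors = 15),
               "n_neighbors")

  # duplicated cells land (numerically) together in the PCA embedding
  dup <- cbind(feats, DUPCELL = feats[, 1])
  xyd <- embed_cells(dup, "pca")
  d12 <- sqrt((xyd$dim1[1] - xyd$dim1[ncol(dup)])^2 +
                (xyd$dim2[1] - xyd$dim2[ncol(dup)])^2)
  diam <- max(dist(cbind(xyd$dim1, xyd$dim2)))
  expect_lt(d12, 0.01 * diam)

  # mean silhouette of true types on PCA coordinates
  sil <- vapply(1:3, function(s) {
    sm <- joined_sim(small_cfg(seed = 600L + s))
    lab <- sm$truth$true_type[match(sm$ds$cells, sm$truth$well_id)]
    lab[lab %in% c("epidermis_A", "epidermis_B")] <- "epidermis"
    keep <- lab %in% c("epidermis", "idioblast", "parenchyma")
    xy <- embed_cells(sm$ds$met$layers$batch_z[, keep], "pca")
    mean_silhouette(cbind(xy$dim1, xy$dim2), lab[keep])
  }, numeric(1))
  expect_true(all(sil >= 0.3))
})

test_that("RNA annotation follows detectability and priority rules", {
  wells <- make_wells(4)
  genes <- c("D4H", "DAT", "G8H", "ISY", "NLTP2", "OTHER")
  counts <- matrix(0L, 6, 4, dimnames = list(genes, wells$well_id))
  counts["DAT", 1] <- 3L                      # idioblast
  counts["G8H", 2] <- 1L; counts["NLTP2", 2] <- 5L  # conflict -> priority
  counts["OTHER", 3] <- 10L                   # unassigned
  counts["NLTP2", 4] <- 1L                    # epidermis
  es <- expression_set(counts, stats::setNames(rep(1000, 6), genes))
  ann <- annotate_rna(es)
  expect_equal(ann$rna_label, c("idioblast", "ipap", "unassigned",
                                "epidermis"))
  bad_rules <- tibble::tibble(label = "x", features = list("NOGENE"))
  expect_error(annotate_rna(es, bad_rules), "unknown gene")
})

test_that("metabolite annotation follows presence rules above LOQ", {
  analytes <- c("serpentine", "loganic_acid", "secologanin", "mauritianin")
  conc <- matrix(0, 4, 5, dimnames = list(analytes, sprintf("c%d", 1:5)))
  mask <- matrix(TRUE, 4, 5, dimnames = dimnames(conc))
  conc["serpentine", 1] <- 50; mask["serpentine", 1] <- FALSE
  conc["secologanin", 2] <- 100; mask["secologanin", 2] <- FALSE
  conc["mauritianin", 2] <- 10; mask["mauritianin", 2] <- FALSE
  conc["secologanin", 3] <- 100; mask["secologanin", 3] <- FALSE
  conc["loganic_acid", 4] <- 4e4; mask["loganic_acid", 4] <- FALSE
  # cell 5: signal recorded but below LOQ -> not "present"
  met <- metabolite_matrix(conc, mask)
  ann <- annotate_met(met)
  expect_equal(ann$met_label,
               c("idioblast", "epidermis_mauritianin", "epidermis",
                 "loganic_acid_cell", "unassigned"))
  bad <- tibble::tibble(label = "x", features = list("unobtainium"),
                        require_absent = list(character()))
  expect_error(annotate_met(met, bad), "unknown analyte")
})

test_that("annotation is a pure per-cell function (permutation equivariant)", {
  sim <- joined_sim(small_cfg(seed = 41L))
  ann <- annotate_rna(sim$ds)
  perm <- sample(length(sim$ds$cells))
  es_p <- sim$ds$expr
  es_p$counts <- es_p$counts[, perm]
  ann_p <- annotate_rna(expression_set(es_p$counts, es_p$gene_length_bp))
  expect_equal(ann_p$rna_label, ann$rna_label[perm])
})

test_that("cross-tabulation conserves marginals and computes co-annotation", {
  ann <- tibble::tibble(
    rna_label = c(rep("idioblast", 8), "unassigned", rep("epidermis", 5)),
    met_label = c(rep("idioblast", 9), rep("epidermis", 5)))
  xt <- cross_tabulate(ann)
  expect_equal(sum(xt$table$n), nrow(ann))
  row_sums <- xt$table |> dplyr::group_by(met_label) |>
    dplyr::summarise(n = sum(n))
  expect_equal(sort(row_sums$n), sort(as.integer(table(ann$met_label))))
  expect_true(all(xt$edges$n > 0))
})

test_that("co-annotation fraction reproduces count-based percentages", {
  wells <- make_wells(12)
  genes <- c("D4H", "DAT", "NLTP2")
  counts <- matrix(0L, 3, 12, dimnames = list(genes, wells$well_id))
  counts["D4H", 1:5] <- 2L
  counts["DAT", 6:8] <- 1L
  conc <- matrix(0, 1, 12, dimnames = list("serpentine", wells$well_id))
  conc["serpentine", 1:9] <- 50  # 9 cells bear serpentine; 8 express markers
  met <- metabolite_matrix(conc, conc == 0)
  ds <- join_by_well(expression_set(counts,
                                    stats::setNames(rep(1e3, 3), genes)),
                     met, wells)
  fr <- co_annotation_fraction(ds, "serpentine", c("D4H", "DAT"))
  expect_equal(fr$n_with_analyte, 9)
  expect_equal(fr$n_coexpressing, 8)
  expect_equal(fr$percent, 89)

  # empty metabolite class -> NA percentage
  conc0 <- matrix(0, 1, 12, dimnames = list("serpentine", wells$well_id))
  ds0 <- join_by_well(expression_set(counts,
                                     stats::setNames(rep(1e3, 3), genes)),
                      metabolite_matrix(conc0, conc0 == 0), wells)
  expect_true(is.na(co_annotation_fraction(ds0, "serpentine",
                                           c("D4H", "DAT"))$percent))
})
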