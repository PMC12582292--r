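test_that("Spearman correlations hit exact monotone extremes and midranks", {
  cells <- sprintf("c%d", 1:5)
  conc <- matrix(c(1, 2, 2, 3, 4), 1, 5, dimnames = list("a", cells))
  tpm <- rbind(up = exp(conc[1, ]), down = -conc[1, ]^3,
               tied = c(10, 20, 30, 30, 50))
  colnames(tpm) <- cells
  ct <- spearman_matrix(tpm, conc)
  expect_equal(ct$rho[ct$gene == "up"], 1)
  expect_equal(ct$rho[ct$gene == "down"], -1)
  expect_equal(ct$rho[ct$gene == "tied"],
               spearman_oracle(tpm["tied", ], conc[1, ]), tolerance = 1e-12)
  expect_error(spearman_matrix(tpm[, 1:2], conc[, 1:2, drop = FALSE]),
               ">= 3")
})

test_that("Spearman is invariant under increasing transforms", {
  set.seed(5)
  cells <- sprintf("c%d", 1:30)
  conc <- matrix(rexp(30), 1, 30, dimnames = list("a", cells))
  tpm <- matrix(rnorm(60), 2, 30, dimnames = list(c("g1", "g2"), cells))
  r0 <- spearman_matrix(tpm, conc)$rho
  r_exp <- spearman_matrix(exp(tpm), conc)$rho
  r_cube <- spearman_matrix(tpm, conc^3)$rho
  expect_equal(r_exp, r0, tolerance = 1e-12)
  expect_equal(r_cube, r0, tolerance = 1e-12)
})

test_that("constant vectors give NA rho and ranks stay a permutation", {
  cells <- sprintf("c%d", 1:6)
  conc <- matrix(1:6, 1, 6, dimnames = list("a", cells))
  tpm <- rbind(flat = rep(2, 6), g1 = c(3, 1, 4, 1, 5, 9),
               g2 = c(2, 7, 1, 8, 2, 8))
  colnames(tpm) <- cells
  ct <- spearman_matrix(tpm, conc)
  expect_true(is.na(ct$rho[ct$gene == "flat"]))
  expect_true(is.na(ct$rank[ct$gene == "flat"]))
  expect_setequal(ct$rank[!is.na(ct$rank)], 1:2)
})

test_that("detected-only mode restricts each analyte to quantified cells", {
  cells <- sprintf("c%d", 1:8)
  conc <- matrix(c(0, 0, 0, 0, 1, 2, 3, 4), 1, 8,
                 dimnames = list("a", cells))
  mask <- conc == 0
  tpm <- matrix(c(5, 6, 7, 8, 4, 3, 2, 1), 1, 8,
                dimnames = list("g", cells))
  all_mode <- spearman_matrix(tpm, conc)
  det_mode <- spearman_matrix(tpm, conc, cells = "detected",
                              below_loq = mask)
  expect_equal(det_mode$n_cells, 4L)
  expect_equal(det_mode$rho, -1)
  expect_false(isTRUE(all.equal(all_mode$rho, det_mode$rho)))
})

test_that("rank curves order genes and annotate highlights", {
  cells <- sprintf("c%d", 1:10)
  conc <- matrix(1:10, 1, 10, dimnames = list("a", cells))
  set.seed(2)
  tpm <- matrix(rnorm(50), 5, 10,
                dimnames = list(sprintf("g%d", 1:5), cells))
  tpm["g3", ] <- 1:10  # perfect correlate
  ct <- spearman_matrix(tpm, conc)
  expect_warning(rc <- rank_curve(ct, "a", c("g3", "ghost")), "ghost")
  expect_true(all(diff(rc$rho) <= 0))
  expect_equal(rc$rank[rc$gene == "g3"], 1L)
})

test_that("local regression reproduces lines, flat data, and shrinks CIs", {
  set.seed(3)
  x <- sort(runif(40, 0, 10))
  y <- 2 + 3 * x
  tr <- loess_trend(x, y, span = 0.75)
  expect_true(all(abs(tr$fit - (2 + 3 * tr$conc)) < 1e-6))

  yc <- rep(5, 40)
  trc <- loess_trend(x, yc)
  expect_true(all(abs(trc$fit - 5) < 1e-9))
  trc_big <- loess_trend(rep(x, 4), rep(yc, 4))
  expect_lt(mean(trc_big$ci_half_width), mean(trc$ci_half_width))
  expect_true(all(tr$ci_half_width >= 0))
  expect_true(all(diff(tr$conc) > 0))
  expect_error(loess_trend(x[1:5], y[1:5]), ">= 10")
})

test_that("transporter networks pick top/bottom correlates per analyte", {
  set.seed(8)
  cells <- sprintf("c%d", 1:30)
  conc <- matrix(rexp(30), 1, 30, dimnames = list("a", cells))
  genes <- sprintf("T%02d", 1:40)
  tpm <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(genes, cells))
  ct <- spearman_matrix(tpm, conc)
  net <- build_transporter_network(ct, genes, top_k = 15, bottom_k = 15)
  expect_equal(nrow(net), 30)
  # independent sort oracle
  rho <- ct$rho[match(genes, ct$gene)]
  top_o <- genes[order(-rho)][1:15]
  bot_o <- genes[order(rho)][1:15]
  expect_setequal(net$transporter[net$sign == "positive"], top_o)
  expect_setequal(net$transporter[net$sign == "negative"], bot_o)
  expect_equal(sum(attr(net, "degree")), nrow(net))

  # fewer transporters than k: all linked as the positive set
  net10 <- build_transporter_network(ct, genes[1:10], top_k = 15,
                                     bottom_k = 15)
  expect_setequal(net10$transporter[net10$sign == "positive"], genes[1:10])

  # NA rho excluded from the ranking
  tpm_na <- rbind(tpm, TFLAT = rep(1, 30))
  ct_na <- spearman_matrix(tpm_na, conc)
  net_na <- build_transporter_network(ct_na, c(genes, "TFLAT"))
  expect_false("TFLAT" %in% net_na$transporter)

  expect_error(build_transporter_network(ct, character()), "empty")
})

test_that("network export round-trips through SIF and GraphML", {
  net <- structure(
    tibble::tibble(transporter = c("T1", "T2", "T1"),
                   analyte = c("a", "a", "b"),
                   rho = c(0.9, -0.8, 0.5),
                   sign = c("positive", "negative", "positive")),
    class = c("transporter_network", "tbl_df", "tbl", "data.frame"))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net[1, ], sif, "sif")
  expect_length(readLines(sif), 1L)
  export_network(net, sif, "sif")
  back <- read_sif(sif)
  expect_setequal(paste(back$transporter, back$sign, back$analyte),
                  paste(net$transporter, net$sign, net$analyte))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  ed <- igraph::as_data_frame(g, "edges")
  expect_setequal(paste(ed$from, ed$to), paste(net$transporter, net$analyte))
  vs <- igraph::as_data_frame(g, "vertices")
  expect_equal(stats::setNames(vs$degree, vs$name)[c("T1", "T2")],
               c(T1 = 2, T2 = 1))
})

test_that("z-score heatmap matrices cluster duplicates together", {
  sim <- joined_sim(small_cfg(seed = 50L))
  hm <- zscore_heatmap_matrix(sim$ds, c("D4H", "DAT", "NLTP2"),
                              c("serpentine", "secologanin"))
  nonconst <- apply(hm$z, 1, stats::sd) > 0
  expect_true(all(abs(rowMeans(hm$z[nonconst, ])) < 1e-9))
  expect_true(all(abs(apply(hm$z[nonconst, ], 1, stats::sd) - 1) < 1e-9))
  expect_setequal(hm$col_order, sim$ds$cells)
  expect_error(zscore_heatmap_matrix(sim$ds, "NOGENE", "serpentine"),
               "unknown feature")
})

test_that("average-linkage order matches a hand-computed dendrogram", {
  # 1-D points {0, 1, 10, 11}: average linkage merges (0,1), then (10,11),
  # then the two pairs; adjacent leaf pairs must be {p1,p2} and {p3,p4}
  x <- matrix(c(0, 1, 10, 11), 4, 1,
              dimnames = list(sprintf("p%d", 1:4), "d"))
  hc <- stats::hclust(stats::dist(x), method = "average")
  expect_equal(sort(hc$height), c(1, 1, 10))
  merged_first <- sort(as.numeric(-hc$merge[1, ]))
  merged_second <- sort(as.numeric(-hc$merge[2, ]))
  expect_true(identical(merged_first, c(1, 2)) ||
                identical(merged_first, c(3, 4)))
  expect_setequal(c(merged_first, merged_second), 1:4)
})

test_that("Wilcoxon DE: exact balanced and extreme cases, BH monotone", {
  cells <- sprintf("c%d", 1:6)
  m <- matrix(c(1, 2, 3, 1, 2, 3,
                1, 2, 3, 4, 5, 6), 2, 6, byrow = TRUE,
              dimnames = list(c("same", "shift"), cells))
  de <- wilcoxon_de(m, cells[1:3], cells[4:6])
  expect_equal(de$p_value[de$gene == "same"], 1)
  expect_equal(de$p_value[de$gene == "shift"], 0.1)
  expect_true(all(de$p_adjusted >= de$p_value - 1e-12))
  expect_true(all(de$p_adjusted <= 1))
  ord <- order(de$p_value)
  expect_true(all(diff(de$p_adjusted[ord]) >= -1e-12))

  expect_error(wilcoxon_de(m, cells[1:3], cells[3:5]), "overlap")
  expect_error(wilcoxon_de(m, cells[1:2], cells[3:6]), ">= 3")
})

test_that("designed subtype genes separate the two epidermal subclusters", {
  sim <- joined_sim(small_cfg(seed = 51L))
  ml <- annotate_met(sim$ds)
  a <- ml$well_id[ml$met_label == "epidermis_mauritianin"]
  b <- ml$well_id[ml$met_label == "epidermis"]
  de <- wilcoxon_de(sim$ds$expr$layers$lognorm, a, b)
  top <- de$gene[order(de$p_adjusted)][1:10]
  expect_gt(length(intersect(top, attr(sim$expr, "de_genes"))), 5)
  expect_gt(de$log2_fc[de$gene == "FLS1"], 1)
})
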