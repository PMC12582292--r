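#' Gene-metabolite Spearman correlation table
#'
#' Spearman correlation (midranks for ties) between each gene's TPM and each
#' analyte's concentration across the jointly profiled cells. Below-LOQ
#' concentrations enter as 0 by default — the presence/absence contrast is
#' part of the signal; `cells = "detected"` restricts each analyte's
#' correlation to the cells in which it was quantified.
#'
#' @param tpm Gene x cell matrix.
#' @param conc Analyte x cell matrix (same cells; order may differ).
#' @param cells `"all"` (default) or `"detected"`.
#' @param below_loq Optional logical mask matching `conc`, required for
#'   `cells = "detected"`.
#' @return A tibble of class `correlation_table`: `gene`, `analyte`, `rho`,
#'   `n_cells`, `rank` (1 = most positive rho within the analyte; NA rhos
#'   unranked). Constant vectors give `rho = NA`.
#' @export
spearman_matrix <- function(tpm, conc, cells = c("all", "detected"),
                            below_loq = NULL) {
  cells <- match.arg(cells)
  shared <- intersect(colnames(tpm), colnames(conc))
  if (length(shared) < 3) stop("need >= 3 shared cells", call. = FALSE)
  tpm <- tpm[, shared, drop = FALSE]
  conc <- conc[, shared, drop = FALSE]
  inform_stage("spearman_matrix", sprintf(
    "%d genes x %d analytes over %d cells (%s-cells mode)", nrow(tpm),
    nrow(conc), length(shared), cells))
  res <- purrr::map_dfr(rownames(conc), function(a) {
    y <- conc[a, ]
    use <- if (cells == "detected") {
      if (is.null(below_loq)) stop("`below_loq` needed for detected mode",
                                   call. = FALSE)
      !below_loq[a, shared]
    } else rep(TRUE, length(y))
    if (sum(use) < 3) {
      return(tibble::tibble(gene = rownames(tpm), analyte = a,
                            rho = NA_real_, n_cells = sum(use)))
    }
    rho <- suppressWarnings(
      stats::cor(t(tpm[, use, drop = FALSE]), y[use], method = "spearman"))
    tibble::tibble(gene = rownames(tpm), analyte = a, rho = as.numeric(rho),
                   n_cells = sum(use))
  })
  res <- res |>
    dplyr::group_by(.data$analyte) |>
    dplyr::mutate(rank = dplyr::if_else(
      is.na(.data$rho), NA_integer_,
      as.integer(rank(-.data$rho, ties.method = "first",
                      na.last = "keep")))) |>
    dplyr::ungroup()
  structure(res, class = c("correlation_table", class(res)))
}

#' Correlation rank curve for one analyte
#'
#' Genes sorted by descending rho (the rank-plot view of a correlation
#' screen), with optional highlighted genes annotated at their ranks.
#'
#' @param table A `correlation_table`.
#' @param analyte Analyte name.
#' @param highlight_genes Genes to flag; unknown genes are skipped with a
#'   warning.
#' @return Tibble: `rank`, `gene`, `rho`, `highlight`.
#' @export
rank_curve <- function(table, analyte, highlight_genes = character()) {
  stopifnot(analyte %in% table$analyte)
  sub <- table |>
    dplyr::filter(.data$analyte == !!analyte, !is.na(.data$rho)) |>
    dplyr::arrange(.data$rank)
  missing <- setdiff(highlight_genes, sub$gene)
  if (length(missing) > 0) {
    warning("highlight gene(s) not in table: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(rank = sub$rank, gene = sub$gene, rho = sub$rho,
                 highlight = sub$gene %in% highlight_genes)
}

#' Local-regression trend of expression against concentration
#'
#' Locally weighted linear regression (tricube weights, degree 1) of TPM on
#' concentration, evaluated on an even grid over the observed range, with a
#' pointwise 95% confidence band (fit +/- 1.96 SE).
#'
#' @param conc Per-cell concentrations.
#' @param tpm Per-cell expression of one gene (TPM).
#' @param span LOESS span (default 0.75).
#' @param grid_size Grid points (default 100).
#' @return Tibble of class `trend_curve`: `conc`, `fit`, `ci_half_width`.
#' @export
loess_trend <- function(conc, tpm, span = 0.75, grid_size = 100) {
  stopifnot(length(conc) == length(tpm))
  if (length(conc) < 10) {
    stop("need >= 10 cells; consider relaxing presence filtering",
         call. = FALSE)
  }
  df <- data.frame(conc = conc, tpm = tpm)
  fit <- stats::loess(tpm ~ conc, data = df, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(conc), max(conc), length.out = grid_size)
  pred <- stats::predict(fit, newdata = data.frame(conc = grid), se = TRUE)
  out <- tibble::tibble(conc = grid, fit = as.numeric(pred$fit),
                        ci_half_width = 1.96 * as.numeric(pred$se.fit))
  structure(out, class = c("trend_curve", class(out)), span = span)
}

#' Build a transporter-metabolite bipartite network
#'
#' Per analyte, connects the `top_k` most positively and `bottom_k` most
#' negatively correlated transporters (NA rhos excluded; ties at the cutoff
#' broken by gene ID lexical order and logged).
#'
#' @param table A `correlation_table`.
#' @param transporters Character vector of transporter gene IDs.
#' @param top_k,bottom_k Edges per analyte per sign (defaults 15 each).
#' @return A tibble of class `transporter_network`: `transporter`, `analyte`,
#'   `rho`, `sign` (`"positive"`/`"negative"`), with attribute `degree`
#'   (named per-transporter edge counts).
#' @export
build_transporter_network <- function(table, transporters, top_k = 15,
                                      bottom_k = 15) {
  if (length(transporters) == 0) stop("empty transporter list",
                                      call. = FALSE)
  sub <- dplyr::filter(table, .data$gene %in% transporters,
                       !is.na(.data$rho))
  if (nrow(sub) == 0) {
    stop("no transporter has a defined correlation", call. = FALSE)
  }
  pick <- function(d, k, decreasing) {
    ord <- order(if (decreasing) -d$rho else d$rho, d$gene)
    kth <- min(k, nrow(d))
    if (nrow(d) > kth && d$rho[ord[kth]] == d$rho[ord[kth + 1]]) {
      inform_stage("build_transporter_network", sprintf(
        "tie at the %d-th %s rho for %s broken by gene ID", kth,
        if (decreasing) "highest" else "lowest", d$analyte[1]))
    }
    d[ord[seq_len(kth)], ]
  }
  edges <- sub |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(function(d, key) {
      d$analyte <- key$analyte
      top <- pick(d, top_k, TRUE)
      top$sign <- "positive"
      bot <- pick(d[!(d$gene %in% top$gene), ], bottom_k, FALSE)
      bot$sign <- if (nrow(bot)) "negative" else character(0)
      dplyr::bind_rows(top, bot)[, c("gene", "rho", "sign")]
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(transporter = "gene") |>
    dplyr::select("transporter", "analyte", "rho", "sign")
  deg <- table(edges$transporter)
  out <- structure(edges,
                   class = c("transporter_network", class(edges)))
  attr(out, "degree") <- stats::setNames(as.integer(deg), names(deg))
  out
}

#' Export a transporter network to SIF or GraphML
#'
#' SIF lines are `transporter <sign> analyte`; GraphML carries `rho` as an
#' edge attribute and the node `degree` and `part` (transporter/analyte) as
#' node attributes. Re-importing reproduces the edge multiset exactly.
#'
#' @param net A `transporter_network`.
#' @param path Output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (nrow(net) == 0) stop("empty network", call. = FALSE)
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", net$transporter, net$sign, net$analyte),
               path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = net$transporter, to = net$analyte, rho = net$rho,
                 sign = net$sign),
      directed = FALSE,
      vertices = data.frame(
        name = c(unique(net$transporter), unique(net$analyte)),
        part = c(rep("transporter", length(unique(net$transporter))),
                 rep("analyte", length(unique(net$analyte))))))
    igraph::V(g)$degree <- igraph::degree(g)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a SIF network file
#'
#' @param path SIF file written by [export_network()].
#' @return Tibble: `transporter`, `sign`, `analyte`.
#' @export
read_sif <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("transporter", "sign", "analyte"),
                           stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' Stacked gene + metabolite z-score matrix with clustering orders
#'
#' Genes are z-scored over cells from the log-normalized layer; analytes from
#' the log10 layer. Rows and columns are ordered by average-linkage
#' hierarchical clustering on Euclidean distance (the heatmap view of the
#' joint dataset).
#'
#' @param dataset A `multiomic_dataset` with `lognorm` and `log10` layers.
#' @param genes,analytes Features to include.
#' @return A list: `z` (feature x cell matrix), `row_order`, `col_order`
#'   (leaf orders), `row_hclust`, `col_hclust`.
#' @export
zscore_heatmap_matrix <- function(dataset, genes, analytes) {
  miss <- c(setdiff(genes, rownames(dataset$expr$layers$lognorm)),
            setdiff(analytes, rownames(dataset$met$layers$log10)))
  if (length(miss) > 0) {
    stop("unknown feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  gz <- scale_rows(dataset$expr$layers$lognorm[genes, , drop = FALSE])
  az <- scale_rows(dataset$met$layers$log10[analytes, , drop = FALSE])
  z <- rbind(gz, az)
  const <- apply(z, 1, function(r) all(r == r[1]))
  if (any(const)) {
    warning("constant feature(s) z-scored to 0: ",
            paste(rownames(z)[const], collapse = ", "), call. = FALSE)
  }
  rh <- stats::hclust(stats::dist(z), method = "average")
  ch <- stats::hclust(stats::dist(t(z)), method = "average")
  list(z = z, row_order = rownames(z)[rh$order],
       col_order = colnames(z)[ch$order], row_hclust = rh, col_hclust = ch)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-normalized expression.
#' When both groups have at most 10 cells the p-value is computed by full
#' enumeration of every assignment of the pooled midranks to group A
#' (two-sided as the probability of a rank-sum at least as far from its null
#' mean as observed), which stays exact under ties; larger groups use the
#' normal approximation with continuity and tie correction. Benjamini-
#' Hochberg adjustment across genes; log2 fold change of de-logged group
#' means with a pseudocount of 1.
#'
#' @param lognorm Gene x cell log-normalized matrix.
#' @param group_a,group_b Disjoint character vectors of cell IDs (>= 3 each).
#' @return A tibble of class `de_result`: `gene`, `mean_a`, `mean_b`,
#'   `log2_fc`, `statistic`, `p_value`, `p_adjusted`.
#' @export
wilcoxon_de <- function(lognorm, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap", call. = FALSE)
  }
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs >= 3 cells", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(lognorm))
  if (length(miss) > 0) {
    stop("unknown cell(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  a <- lognorm[, group_a, drop = FALSE]
  b <- lognorm[, group_b, drop = FALSE]
  na <- length(group_a)
  exact <- na <= 10 && length(group_b) <= 10
  if (exact) {
    # group identity is fixed across genes, so enumerate the assignments once
    idx <- utils::combn(na + length(group_b), na)
    res <- purrr::map_dfr(rownames(lognorm), function(g) {
      r <- rank(c(a[g, ], b[g, ]), ties.method = "average")
      w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
      w_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
      mu <- mean(w_all)
      p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
      tibble::tibble(gene = g, statistic = w_obs, p_value = min(1, p))
    })
  } else {
    res <- purrr::map_dfr(rownames(lognorm), function(g) {
      wt <- suppressWarnings(stats::wilcox.test(
        a[g, ], b[g, ], alternative = "two.sided", exact = FALSE,
        correct = TRUE))
      tibble::tibble(gene = g, statistic = unname(wt$statistic),
                     p_value = wt$p.value)
    })
  }
  mean_a <- rowMeans(expm1(a))
  mean_b <- rowMeans(expm1(b))
  out <- res |>
    dplyr::mutate(mean_a = mean_a[.data$gene], mean_b = mean_b[.data$gene],
                  log2_fc = log2((.data$mean_a + 1) / (.data$mean_b + 1)),
                  p_adjusted = stats::p.adjust(.data$p_value, "BH")) |>
    dplyr::select("gene", "mean_a", "mean_b", "log2_fc", "statistic",
                  "p_value", "p_adjusted")
  structure(out, class = c("de_result", class(out)))
}

#' @export
tidy.de_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 n_significant_05 = sum(x$p_adjusted <= 0.05, na.rm = TRUE),
                 min_p_adjusted = min(x$p_adjusted, na.rm = TRUE))
}
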