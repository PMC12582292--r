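#' Quality-control filter for single-cell expression
#'
#' Keeps cells that (i) come from single-cell wells and (ii) detect strictly
#' more than `min_genes` and strictly fewer than `max_genes` genes, where a
#' gene is detected when its raw count exceeds 0. Idempotent: filtering the
#' result again changes nothing.
#'
#' @param expr An [expression_set].
#' @param wells Well metadata tibble; every cell column must have a row.
#' @param min_genes,max_genes Exclusive bounds on detected genes (defaults
#'   1,000 and 10,000).
#' @return A list: `expr` (filtered [expression_set]) and `report` (tibble:
#'   `well_id`, `status`, `genes_detected`, `kept`, plus attributes
#'   `n_input`, `n_kept`, `min_genes`, `max_genes`).
#' @export
qc_filter <- function(expr, wells, min_genes = 1000, max_genes = 10000) {
  cells <- colnames(expr$counts)
  miss <- setdiff(cells, wells$well_id)
  if (length(miss) > 0) {
    stop("no well metadata for cell(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  status <- wells$status[match(cells, wells$well_id)]
  detected <- unname(colSums(expr$counts > 0))
  kept <- status == "single" & detected > min_genes & detected < max_genes
  report <- tibble::tibble(well_id = cells, status = status,
                           genes_detected = as.integer(detected),
                           kept = kept)
  attr(report, "n_input") <- length(cells)
  attr(report, "n_kept") <- sum(kept)
  attr(report, "min_genes") <- min_genes
  attr(report, "max_genes") <- max_genes
  out <- expression_set(expr$counts[, kept, drop = FALSE],
                        expr$gene_length_bp)
  inform_stage("qc_filter", sprintf(
    "kept %d of %d cells (%.1f%%); bounds (%d, %d) exclusive",
    sum(kept), length(cells), 100 * mean(kept), min_genes, max_genes))
  list(expr = out, report = report)
}

#' Transcripts per million from counts and gene lengths
#'
#' `tpm[g,c] = 1e6 * (count[g,c] / len_kb[g]) / sum_g'(count[g',c] /
#' len_kb[g'])`. Columns of all-zero cells stay all-zero (with a warning).
#'
#' @param expr An [expression_set].
#' @return Gene x cell TPM matrix; every non-empty column sums to 1e6.
#' @export
compute_tpm <- function(expr) {
  rate <- expr$counts / (expr$gene_length_bp / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero cell(s); TPM column left at zero",
            call. = FALSE)
    tot[tot == 0] <- 1
  }
  sweep(rate, 2, tot, `/`) * 1e6
}

#' Log-normalize counts
#'
#' `x[g,c] = ln(1 + scale_factor * count[g,c] / total[c])`, the standard
#' library-size normalization with a pseudocount of 1.
#'
#' @param expr An [expression_set] or a counts matrix.
#' @param scale_factor Target library size (default 10,000).
#' @return Gene x cell matrix of log-normalized expression.
#' @export
log_normalize <- function(expr, scale_factor = 10000) {
  counts <- if (inherits(expr, "expression_set")) expr$counts else expr
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total cell(s); column left at zero",
            call. = FALSE)
    tot[tot == 0] <- 1
  }
  log1p(sweep(counts, 2, tot, `/`) * scale_factor)
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing selection: regress log10(variance) on log10(mean)
#' across genes with a LOESS fit (span 0.3), standardize each gene's counts
#' by the fitted standard deviation with values clipped at sqrt(n_cells),
#' rank genes by the variance of the standardized values and return the top
#' `n`. Ties break by gene ID lexical order.
#'
#' @param expr An [expression_set] or counts matrix.
#' @param n Number of genes to return (default 500).
#' @return Character vector of gene IDs, ordered by decreasing standardized
#'   variance. If fewer than `n` genes vary, all varying genes are returned
#'   with a warning.
#' @export
select_variable_genes <- function(expr, n = 500) {
  counts <- if (inherits(expr, "expression_set")) expr$counts else expr
  mu <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  use <- mu > 0 & v > 0
  if (sum(use) < n) {
    warning("only ", sum(use), " non-constant genes available", call. = FALSE)
    n <- sum(use)
  }
  fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = 0.3,
                      degree = 2)
  sd_fit <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(ncol(counts))
  std_var <- vapply(seq_along(sd_fit), function(i) {
    z <- (counts[which(use)[i], ] - mu[use][i]) / sd_fit[i]
    z <- pmin(z, clip)
    stats::var(z)
  }, numeric(1))
  genes <- rownames(counts)[use]
  ord <- order(-std_var, genes)
  genes[ord][seq_len(n)]
}

#' Scale expression rows to z-scores
#'
#' @param mat Gene x cell matrix (typically log-normalized, variable genes).
#' @return Matrix with each non-constant row centered to mean 0, sd 1
#'   (sample sd); constant rows become 0.
#' @export
scale_rows <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  sweep(sweep(mat, 1, mu, `-`), 1, s, `/`)
}

#' Derive the standard normalized layers
#'
#' Convenience wrapper: TPM, log-normalized, variable genes and the scaled
#' variable-gene layer, stored on the [expression_set].
#'
#' @param expr An [expression_set] (typically QC-filtered).
#' @param n_variable Number of variable genes (default 500).
#' @param scale_factor Passed to [log_normalize()].
#' @return The [expression_set] with `layers$tpm`, `layers$lognorm`,
#'   `layers$scaled` and attribute-free `variable_genes` element filled in.
#' @export
normalize_expression <- function(expr, n_variable = 500,
                                 scale_factor = 10000) {
  expr$layers$tpm <- compute_tpm(expr)
  expr$layers$lognorm <- log_normalize(expr, scale_factor)
  vg <- select_variable_genes(expr, n_variable)
  expr$variable_genes <- vg
  expr$layers$scaled <- scale_rows(expr$layers$lognorm[vg, , drop = FALSE])
  expr
}

#' Spearman concordance of pseudobulk with a bulk profile
#'
#' Sums counts over kept cells, TPM-normalizes the sum, and correlates with a
#' per-gene bulk profile over genes detected in either (Spearman).
#'
#' @param expr An [expression_set] of kept cells.
#' @param bulk_profile Named per-gene numeric vector (counts or TPM).
#' @return Spearman rho (single number).
#' @export
pseudobulk_compare <- function(expr, bulk_profile) {
  shared <- intersect(rownames(expr$counts), names(bulk_profile))
  if (length(shared) < 10) stop("fewer than 10 shared genes", call. = FALSE)
  pseudo <- rowSums(expr$counts[shared, , drop = FALSE])
  rate <- pseudo / (expr$gene_length_bp[shared] / 1000)
  pseudo_tpm <- rate / sum(rate) * 1e6
  bulk <- bulk_profile[shared]
  keep <- pseudo_tpm > 0 | bulk > 0
  stats::cor(pseudo_tpm[keep], bulk[keep], method = "spearman")
}
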