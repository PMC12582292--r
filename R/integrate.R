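#' Join expression and metabolite data by well identity
#'
#' Each cell's two measurements come from the same physical well, so the join
#' key is the well ID, never position. Cells present in only one modality are
#' reported, not silently dropped.
#'
#' @param expr An [expression_set] (QC-filtered, typically with layers from
#'   [normalize_expression()]).
#' @param met A [metabolite_matrix].
#' @param wells Well metadata tibble.
#' @return A list of class `multiomic_dataset`: `cells` (intersection, in
#'   expression order), `expr`, `met` (both subset to the shared cells),
#'   `batch` (named vector), `drop_report` (tibble: well_id, modality).
#' @export
join_by_well <- function(expr, met, wells) {
  ec <- colnames(expr$counts)
  mc <- colnames(met$conc_uM)
  if (anyDuplicated(mc)) stop("duplicated well_id in metabolite matrix",
                              call. = FALSE)
  cells <- ec[ec %in% mc]
  if (length(cells) == 0) stop("no shared cells between modalities",
                               call. = FALSE)
  drop_report <- dplyr::bind_rows(
    tibble::tibble(well_id = setdiff(ec, mc), modality = "expression_only"),
    tibble::tibble(well_id = setdiff(mc, ec), modality = "metabolite_only"))
  expr$counts <- expr$counts[, cells, drop = FALSE]
  expr$layers <- lapply(expr$layers, function(m) m[, cells, drop = FALSE])
  met$conc_uM <- met$conc_uM[, cells, drop = FALSE]
  met$below_loq <- met$below_loq[, cells, drop = FALSE]
  met$batch <- met$batch[cells]
  met$layers <- lapply(met$layers, function(m) m[, cells, drop = FALSE])
  batch <- met$batch
  if (is.null(batch) || anyNA(batch)) {
    batch <- stats::setNames(wells$batch[match(cells, wells$well_id)], cells)
  }
  inform_stage("join_by_well", sprintf(
    "%d shared cells; %d dropped (%d expression-only, %d metabolite-only)",
    length(cells), nrow(drop_report),
    sum(drop_report$modality == "expression_only"),
    sum(drop_report$modality == "metabolite_only")))
  structure(list(cells = cells, expr = expr, met = met, batch = batch,
                 drop_report = drop_report),
            class = "multiomic_dataset")
}

#' @export
print.multiomic_dataset <- function(x, ...) {
  cat(sprintf("<multiomic_dataset> %d cells; %d genes; %d analytes\n",
              length(x$cells), nrow(x$expr$counts), nrow(x$met$conc_uM)))
  invisible(x)
}

#' Normalize metabolite concentrations for embedding
#'
#' Log layer: `log10(1 + conc_uM)` (bounded at 0 for absent analytes). Z
#' layer: the log layer standardized per analyte within each batch (sample
#' sd, n-1); analytes constant within a batch get z = 0, and single-cell
#' batches get z = 0 with a warning.
#'
#' @param met A [metabolite_matrix] with batch labels.
#' @return The [metabolite_matrix] with `layers$log10` and `layers$batch_z`.
#' @export
normalize_metabolites <- function(met) {
  lg <- log10(1 + met$conc_uM)
  z <- lg
  for (b in unique(met$batch)) {
    idx <- which(met$batch == b)
    if (length(idx) < 2) {
      warning("batch ", b, " has a single cell; z set to 0", call. = FALSE)
      z[, idx] <- 0
      next
    }
    sub <- lg[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1, stats::sd)
    s[s == 0 | is.na(s)] <- Inf  # constant analyte within batch -> z = 0
    z[, idx] <- sweep(sweep(sub, 1, mu, `-`), 1, s, `/`)
  }
  met$layers$log10 <- lg
  met$layers$batch_z <- z
  met
}

#' Two-dimensional embedding of cells
#'
#' UMAP (via uwot, fixed seed) or a deterministic PCA fallback whose exact
#' coordinates do not depend on any stochastic library internals. The RNA
#' embedding conventionally uses the scaled variable-gene layer; the
#' metabolite embedding the batch-z layer of the quantified analytes.
#'
#' @param features Feature x cell matrix.
#' @param method `"umap"` or `"pca"`.
#' @param seed Integer seed (UMAP only).
#' @param n_neighbors,min_dist UMAP parameters (defaults 15, 0.1).
#' @return Tibble: `well_id`, `dim1`, `dim2`.
#' @export
embed_cells <- function(features, method = c("umap", "pca"), seed = 1L,
                        n_neighbors = 15, min_dist = 0.1) {
  method <- match.arg(method)
  n <- ncol(features)
  x <- t(features)
  if (method == "umap") {
    if (n < n_neighbors + 1) {
      stop("need at least n_neighbors + 1 = ", n_neighbors + 1,
           " cells; reduce n_neighbors", call. = FALSE)
    }
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("package 'uwot' is required for method = \"umap\"; ",
           "use method = \"pca\"", call. = FALSE)
    }
    set.seed(seed)
    xy <- uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                     n_threads = 1, n_sgd_threads = 1)
  } else {
    if (n < 3) stop("need at least 3 cells", call. = FALSE)
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    xy <- pc$x[, 1:2, drop = FALSE]
    # deterministic sign convention: largest-|loading| element positive
    for (j in 1:2) {
      r <- pc$rotation[, j]
      if (r[which.max(abs(r))] < 0) xy[, j] <- -xy[, j]
    }
  }
  stopifnot(all(is.finite(xy)))
  tibble::tibble(well_id = colnames(features), dim1 = xy[, 1], dim2 = xy[, 2])
}

#' Default marker rules for dual annotation
#'
#' RNA rules (priority order; "detectable" = raw count >= 1): D4H or DAT ->
#' idioblast; G8H or ISY -> IPAP; NLTP2 -> epidermis. Metabolite rules
#' (presence = quantified above LOQ): serpentine -> idioblast; loganic acid
#' -> loganic-acid cell; secologanin + mauritianin -> mauritianin epidermis;
#' secologanin alone -> epidermis. Idioblast markers take priority because
#' they are the most cell-type-exclusive.
#'
#' @return A list with `rna` and `met` rule tibbles (label, features
#'   list-column, and for metabolite rules a `require_absent` list-column).
#' @export
default_marker_rules <- function() {
  list(
    rna = tibble::tibble(
      label = c("idioblast", "ipap", "epidermis"),
      features = list(c("D4H", "DAT"), c("G8H", "ISY"), "NLTP2")),
    met = tibble::tibble(
      label = c("idioblast", "loganic_acid_cell", "epidermis_mauritianin",
                "epidermis"),
      features = list("serpentine", "loganic_acid",
                      c("secologanin", "mauritianin"), "secologanin"),
      require_absent = list(character(), character(), character(),
                            "mauritianin"))
  )
}

#' RNA-rule cell-type annotation
#'
#' Assigns each cell the label of the first rule (in priority order) with at
#' least one detectable marker gene (raw count >= 1). Cells matching no rule
#' are `unassigned`. Conflicts (a cell matching several rules) are resolved
#' by priority and logged.
#'
#' @param dataset A `multiomic_dataset` (or an [expression_set]).
#' @param rules Rule list from [default_marker_rules()] (its `rna` element).
#' @return Tibble: `well_id`, `rna_label`.
#' @export
annotate_rna <- function(dataset, rules = default_marker_rules()$rna) {
  counts <- if (inherits(dataset, "multiomic_dataset")) {
    dataset$expr$counts
  } else dataset$counts
  unknown <- setdiff(unlist(rules$features), rownames(counts))
  if (length(unknown) > 0) {
    stop("rule references unknown gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hit <- vapply(seq_len(nrow(rules)), function(i) {
    colSums(counts[rules$features[[i]], , drop = FALSE] >= 1) > 0
  }, logical(ncol(counts)))
  hit <- matrix(hit, ncol = nrow(rules))
  n_hits <- rowSums(hit)
  if (any(n_hits > 1)) {
    inform_stage("annotate_rna", sprintf(
      "%d cell(s) matched multiple rules; resolved by priority order",
      sum(n_hits > 1)))
  }
  label <- apply(hit, 1, function(h) {
    if (any(h)) rules$label[which(h)[1]] else "unassigned"
  })
  tibble::tibble(well_id = colnames(counts), rna_label = label)
}

#' Metabolite-rule cell-type annotation
#'
#' Presence of an analyte = quantified above its LOQ (mask `FALSE` and
#' concentration > 0). Rules apply in priority order; a rule may additionally
#' require analytes to be absent (e.g. "secologanin alone").
#'
#' @param dataset A `multiomic_dataset` (or a [metabolite_matrix]).
#' @param rules Rule tibble from [default_marker_rules()] (its `met`
#'   element).
#' @return Tibble: `well_id`, `met_label`.
#' @export
annotate_met <- function(dataset, rules = default_marker_rules()$met) {
  met <- if (inherits(dataset, "multiomic_dataset")) dataset$met else dataset
  unknown <- setdiff(unlist(c(rules$features, rules$require_absent)),
                     rownames(met$conc_uM))
  if (length(unknown) > 0) {
    stop("rule references unknown analyte(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  present <- met$conc_uM > 0 & !met$below_loq
  label <- vapply(seq_len(ncol(present)), function(j) {
    for (i in seq_len(nrow(rules))) {
      need <- rules$features[[i]]
      veto <- rules$require_absent[[i]]
      if (all(present[need, j]) && !any(present[veto, j])) {
        return(rules$label[i])
      }
    }
    "unassigned"
  }, character(1))
  tibble::tibble(well_id = colnames(met$conc_uM), met_label = label)
}

#' Dual annotation with embeddings
#'
#' Runs both rule sets and both embeddings and returns one row per cell.
#'
#' @param dataset A `multiomic_dataset` whose expression has a `scaled` layer
#'   and whose metabolites have a `batch_z` layer.
#' @param rules Full rule list from [default_marker_rules()].
#' @param method Embedding method, see [embed_cells()].
#' @param seed Embedding seed.
#' @return Tibble of class `annotation_table`: `well_id`, `rna_label`,
#'   `met_label`, `rna_dim1/2`, `met_dim1/2`.
#' @export
annotate_cells <- function(dataset, rules = default_marker_rules(),
                           method = "umap", seed = 1L) {
  rna <- annotate_rna(dataset, rules$rna)
  met <- annotate_met(dataset, rules$met)
  rna_xy <- embed_cells(dataset$expr$layers$scaled, method, seed)
  met_xy <- embed_cells(dataset$met$layers$batch_z, method, seed)
  out <- rna |>
    dplyr::left_join(met, by = "well_id") |>
    dplyr::left_join(dplyr::rename(rna_xy, rna_dim1 = "dim1",
                                   rna_dim2 = "dim2"), by = "well_id") |>
    dplyr::left_join(dplyr::rename(met_xy, met_dim1 = "dim1",
                                   met_dim2 = "dim2"), by = "well_id")
  structure(out, class = c("annotation_table", class(out)))
}

#' Cross-tabulate the two annotations
#'
#' Counts cells per (RNA label, metabolite label) pair; the nonzero entries
#' are the edge list of the comparison Sankey diagram whose band heights are
#' proportional to cell counts.
#'
#' @param ann An annotation tibble with `rna_label` and `met_label`.
#' @return A list: `table` (tibble rna_label, met_label, n), `edges` (the
#'   nonzero rows), `n_cells`.
#' @export
cross_tabulate <- function(ann) {
  tab <- ann |>
    dplyr::count(.data$rna_label, .data$met_label, name = "n") |>
    tidyr::complete(.data$rna_label, .data$met_label,
                    fill = list(n = 0L))
  list(table = tab, edges = dplyr::filter(tab, .data$n > 0),
       n_cells = nrow(ann))
}

#' Co-annotation fraction of a metabolite with a gene set
#'
#' Of the cells in which `analyte` is present (above LOQ), the percentage
#' that also detect (raw count >= 1) at least one gene of `genes`. Reported
#' rounded half-up to the nearest integer percent; `NA` if no cell carries
#' the analyte.
#'
#' @param dataset A `multiomic_dataset`.
#' @param analyte Analyte name.
#' @param genes Character vector of marker genes.
#' @return A one-row tibble: `analyte`, `n_with_analyte`, `n_coexpressing`,
#'   `percent`.
#' @export
co_annotation_fraction <- function(dataset, analyte, genes) {
  stopifnot(analyte %in% rownames(dataset$met$conc_uM))
  genes <- intersect(genes, rownames(dataset$expr$counts))
  present <- dataset$met$conc_uM[analyte, ] > 0 &
    !dataset$met$below_loq[analyte, ]
  expressing <- colSums(dataset$expr$counts[genes, , drop = FALSE] >= 1) > 0
  n_with <- sum(present)
  n_co <- sum(present & expressing)
  pct <- if (n_with == 0) NA_real_ else floor(100 * n_co / n_with + 0.5)
  tibble::tibble(analyte = analyte, n_with_analyte = n_with,
                 n_coexpressing = n_co, percent = pct)
}
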