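#' Construct a gene-by-cell expression container
#'
#' Bundles a raw count matrix with per-gene lengths and any derived layers
#' (`tpm`, `lognorm`, `scaled`, ...). Counts are genes in rows, cells (well
#' IDs) in columns; all downstream joins are by well ID, never by position.
#'
#' @param counts Non-negative integer matrix, genes x cells, with both
#'   dimnames set.
#' @param gene_length_bp Named numeric vector of gene lengths in base pairs;
#'   must cover every gene in `counts`.
#' @param layers Named list of derived matrices sharing `counts`' dimnames
#'   (possibly with a gene subset, e.g. a scaled variable-gene layer).
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(counts, gene_length_bp, layers = list()) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("gene and cell identifiers must be unique", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral", call. = FALSE)
  }
  gl <- gene_length_bp[rownames(counts)]
  missing <- rownames(counts)[is.na(gl)]
  if (length(missing) > 0) {
    stop("no gene length for: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(gl < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  structure(
    list(counts = counts, gene_length_bp = gl, layers = layers),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d cells; layers: %s\n",
              nrow(x$counts), ncol(x$counts),
              if (length(x$layers)) paste(names(x$layers), collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$counts)

#' Construct an analyte-by-cell intracellular concentration container
#'
#' Concentrations are in uM. Entries censored below the analyte's limit of
#' quantification are recorded as 0 with `below_loq = TRUE`.
#'
#' @param conc_uM Non-negative numeric matrix, analytes x cells, dimnames set.
#' @param below_loq Logical matrix of the same shape; `TRUE` entries must be 0
#'   in `conc_uM`.
#' @param batch Named character vector mapping each cell (column) to its
#'   collection batch.
#' @param layers Named list of derived matrices (e.g. `log10`, `batch_z`).
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(conc_uM, below_loq = NULL, batch = NULL,
                              layers = list()) {
  if (!is.matrix(conc_uM)) conc_uM <- as.matrix(conc_uM)
  if (is.null(rownames(conc_uM)) || is.null(colnames(conc_uM))) {
    stop("`conc_uM` must carry analyte rownames and cell colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(conc_uM))) {
    stop("analyte names must be unique", call. = FALSE)
  }
  if (any(conc_uM < 0)) stop("concentrations must be non-negative",
                             call. = FALSE)
  if (is.null(below_loq)) {
    below_loq <- conc_uM == 0
  }
  stopifnot(identical(dim(below_loq), dim(conc_uM)))
  dimnames(below_loq) <- dimnames(conc_uM)
  if (any(below_loq & conc_uM != 0)) {
    stop("below-LOQ entries must be recorded as 0", call. = FALSE)
  }
  if (is.null(batch)) {
    batch <- stats::setNames(rep("batch1", ncol(conc_uM)), colnames(conc_uM))
  }
  batch <- batch[colnames(conc_uM)]
  if (anyNA(batch)) stop("every cell needs a batch label", call. = FALSE)
  structure(
    list(conc_uM = conc_uM, below_loq = below_loq, batch = batch,
         layers = layers),
    class = "metabolite_matrix"
  )
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf(
    "<metabolite_matrix> %d analytes x %d cells; %.1f%% below LOQ; batches: %s\n",
    nrow(x$conc_uM), ncol(x$conc_uM), 100 * mean(x$below_loq),
    paste(unique(x$batch), collapse = ", ")))
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$conc_uM)

# Internal: validate a well-metadata tibble (one row per plate well).
validate_wells <- function(wells) {
  required <- c("well_id", "plate", "batch", "status", "diameter_um")
  miss <- setdiff(required, names(wells))
  if (length(miss) > 0) {
    stop("well table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(wells$well_id)) {
    dup <- unique(wells$well_id[duplicated(wells$well_id)])
    stop("duplicate well_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_status <- setdiff(unique(wells$status), c("single", "doublet", "empty"))
  if (length(bad_status) > 0) {
    stop("unknown well status: ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  if (any(wells$status == "empty" & !is.na(wells$diameter_um))) {
    stop("empty wells must not carry a cell diameter", call. = FALSE)
  }
  if (any(wells$status != "empty" & is.na(wells$diameter_um))) {
    stop("non-empty wells must carry a cell diameter", call. = FALSE)
  }
  if (any(!is.na(wells$diameter_um) & wells$diameter_um <= 0)) {
    stop("cell diameters must be positive", call. = FALSE)
  }
  tibble::as_tibble(wells)
}
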