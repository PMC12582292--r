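#' Read per-well plate metadata
#'
#' Reads the table produced by the cell-picking stage: one row per plate well
#' with its picked status (`single`, `doublet`, `empty`) and, for non-empty
#' wells, the protoplast diameter measured from the picking images.
#'
#' @param path TSV or CSV file with columns `well_id`, `plate`, `batch`,
#'   `status`, `diameter_um`. Missing diameters may be `NA`, `NaN` or empty.
#' @return A tibble, one row per well, validated (unique well IDs, positive
#'   diameters, no diameter on empty wells).
#' @export
read_well_metadata <- function(path) {
  wells <- read_delim_auto(path)
  wells <- validate_wells(wells)
  wells$diameter_um <- as.numeric(wells$diameter_um)
  inform_stage("read_well_metadata", sprintf(
    "%d wells (%d single, %d doublet, %d empty)", nrow(wells),
    sum(wells$status == "single"), sum(wells$status == "doublet"),
    sum(wells$status == "empty")))
  wells
}

#' Read a gene-by-cell count matrix with gene lengths
#'
#' Accepts either a dense TSV (genes in rows, cells in columns, gene IDs in
#' the first column) or a MatrixMarket coordinate file plus plain-text
#' `<stem>.rownames` / `<stem>.colnames` sidecars (one ID per line, 1-based
#' indices per the MTX standard).
#'
#' @param path_counts Path to the counts TSV or `.mtx` file.
#' @param path_lengths TSV/CSV with columns `gene_id`, `length_bp` covering
#'   every gene in the matrix.
#' @return An [expression_set].
#' @export
read_expression <- function(path_counts, path_lengths) {
  if (grepl("\\.mtx$", path_counts, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path_counts))
    stem <- sub("\\.mtx$", "", path_counts, ignore.case = TRUE)
    rn <- readLines(paste0(stem, ".rownames"))
    cn <- readLines(paste0(stem, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("sidecar name files do not match matrix dimensions", call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
  } else {
    tab <- read_delim_auto(path_counts)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
  }
  if (any(is.na(m))) stop("count matrix contains missing values", call. = FALSE)
  if (any(m < 0)) stop("count matrix contains negative entries", call. = FALSE)
  if (any(abs(m - round(m)) > 1e-8)) {
    stop("count matrix contains non-integer entries", call. = FALSE)
  }
  len <- read_delim_auto(path_lengths)
  if (!all(c("gene_id", "length_bp") %in% names(len))) {
    stop("length table needs columns gene_id, length_bp", call. = FALSE)
  }
  gl <- stats::setNames(as.numeric(len$length_bp), len$gene_id)
  es <- expression_set(m, gl)
  inform_stage("read_expression",
               sprintf("%d genes x %d cells", nrow(m), ncol(m)))
  es
}

#' Read a targeted peak-area table
#'
#' @param path CSV/TSV with an `analyte` column followed by one column per
#'   well (integrated peak areas, arbitrary units).
#' @return Numeric matrix, analytes x wells.
#' @export
read_peak_areas <- function(path) {
  tab <- read_delim_auto(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicate analyte rows", call. = FALSE)
  m
}

#' Read a calibration-standards table
#'
#' @param path CSV/TSV with columns `analyte`, `nominal_conc_uM`,
#'   `replicate`, `area` (long format; one row per replicate injection).
#' @return A tibble grouped implicitly by analyte.
#' @export
read_standards <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("analyte", "nominal_conc_uM", "replicate", "area")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("standards table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Write a tabular result to disk
#'
#' Missing values are serialized as literal `NA`; round-tripping through
#' [read_delim_auto()] reproduces numeric values to better than 1e-9 relative
#' tolerance (full double precision is written).
#'
#' @param obj A data frame, or a matrix (written with a leading ID column).
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @param id_col Name for the leading ID column when `obj` is a matrix.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, format = c("tsv", "csv"), id_col = "id") {
  format <- match.arg(format)
  if (is.matrix(obj)) {
    obj <- tibble::as_tibble(obj, rownames = id_col)
  }
  obj <- tibble::as_tibble(obj)
  delim <- if (format == "tsv") "\t" else ","
  readr::write_delim(obj, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read a delimited table, sniffing the delimiter
#'
#' Accepts `NA`, `NaN` and empty strings as missing values, matching
#' [write_table()].
#'
#' @param path CSV or TSV file.
#' @return A tibble.
#' @export
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, na = c("NA", "NaN", ""),
                    show_col_types = FALSE, progress = FALSE)
}

#' Write an expression count matrix in MatrixMarket form
#'
#' Writes `<stem>.mtx` plus `<stem>.rownames` / `<stem>.colnames` sidecars.
#'
#' @param es An [expression_set].
#' @param stem Output path stem (no extension).
#' @return The `.mtx` path, invisibly.
#' @export
write_expression_mtx <- function(es, stem) {
  m <- Matrix::Matrix(es$counts, sparse = TRUE)
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  writeLines(rownames(es$counts), paste0(stem, ".rownames"))
  writeLines(colnames(es$counts), paste0(stem, ".colnames"))
  invisible(paste0(stem, ".mtx"))
}

#' Read a pipeline configuration file
#'
#' YAML mirroring the arguments of the pipeline stages (QC thresholds, marker
#' rules, aliquot volume, seeds, network size). Values absent from the file
#' fall back to each function's documented default.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$seed) && cfg$seed != as.integer(cfg$seed)) {
    stop("seed must be an integer", call. = FALSE)
  }
  cfg
}

# Internal: stage logging at INFO level, silenced via
# options(scduet.verbose = FALSE).
inform_stage <- function(stage, msg) {
  if (isTRUE(getOption("scduet.verbose", TRUE))) {
    rlang::inform(sprintf("[%s] %s", stage, msg))
  }
  invisible(NULL)
}
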