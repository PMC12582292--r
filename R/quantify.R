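#' Fit per-analyte external calibration curves
#'
#' Ordinary least squares of the mean replicate peak area on the nominal
#' analysis-solution concentration, per analyte. The calibration range is the
#' span of nominal concentrations in the series.
#'
#' Standards whose mean replicate area is zero carry no instrument signal
#' (they sit below the detection floor) and are excluded from the line fit;
#' they remain in the series for LOQ evaluation, where they fail the accuracy
#' check. An analyte with fewer than two concentrations showing signal is
#' returned unusable with a warning.
#'
#' @param standards Tibble with columns `analyte`, `nominal_conc_uM`,
#'   `replicate`, `area` (one row per replicate injection).
#' @return A tibble of class `calibration_curves`: `analyte`, `slope`
#'   (area per uM), `intercept`, `r2`, `range_low_uM`, `range_high_uM`,
#'   `n_points`, `usable` (slope > 0). A non-positive slope is flagged
#'   unusable with a warning, not an error.
#' @export
fit_calibration <- function(standards) {
  need <- c("analyte", "nominal_conc_uM", "replicate", "area")
  stopifnot(all(need %in% names(standards)))
  if (any(standards$area < 0)) stop("peak areas must be non-negative",
                                    call. = FALSE)
  curves <- standards |>
    dplyr::group_by(.data$analyte, .data$nominal_conc_uM) |>
    dplyr::summarise(mean_area = mean(.data$area), .groups = "drop") |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(fit = list(fit_line(.data$nominal_conc_uM,
                                         .data$mean_area)),
                     .groups = "drop") |>
    tidyr::unnest_wider("fit")
  bad_slope <- !curves$usable & !is.na(curves$slope)
  if (any(bad_slope)) {
    warning("non-positive calibration slope for: ",
            paste(curves$analyte[bad_slope], collapse = ", "),
            call. = FALSE)
  }
  structure(curves, class = c("calibration_curves", class(curves)))
}

# Internal: closed-form OLS of y on x with r2 and range. Zero-signal points
# (mean area 0) are excluded from the fit but kept in the reported range
# decision upstream.
fit_line <- function(x, y) {
  if (length(unique(x)) < 2) {
    stop("calibration needs >= 2 distinct nominal concentrations",
         call. = FALSE)
  }
  signal <- y > 0
  if (sum(signal) < 2 || length(unique(x[signal])) < 2) {
    warning("fewer than 2 standards with signal; curve unusable",
            call. = FALSE)
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                range_low_uM = min(x), range_high_uM = max(x),
                n_points = length(unique(x)), usable = FALSE))
  }
  x_all <- x
  x <- x[signal]
  y <- y[signal]
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2,
       range_low_uM = min(x), range_high_uM = max(x),
       n_points = length(unique(x_all)), usable = slope > 0)
}

#' Determine the limit of quantification per analyte
#'
#' LOQ = the lowest calibration standard whose back-calculated mean
#' concentration is accurate within `accuracy_tol` and whose replicate areas
#' have a coefficient of variation at most `cv_tol` (and every higher
#' standard need not be checked: the standard itself qualifies). Analytes
#' with no qualifying standard get `loq_uM = Inf` and are unquantifiable.
#'
#' @param standards Standards tibble (see [fit_calibration()]).
#' @param curves Output of [fit_calibration()] on the same series.
#' @param accuracy_tol Allowed relative deviation of the back-calculated mean
#'   from the nominal concentration (default 0.2, i.e. +/-20%).
#' @param cv_tol Maximum replicate CV (default 0.2).
#' @return `curves` with columns `loq_uM` and `quantifiable` added.
#' @export
determine_loq <- function(standards, curves, accuracy_tol = 0.2,
                          cv_tol = 0.2) {
  loq <- standards |>
    dplyr::left_join(dplyr::select(curves, "analyte", "slope", "intercept"),
                     by = "analyte") |>
    dplyr::group_by(.data$analyte, .data$nominal_conc_uM) |>
    dplyr::summarise(
      back_mean = mean((.data$area - .data$intercept) / .data$slope),
      cv = stats::sd(.data$area) / mean(.data$area),
      .groups = "drop_last") |>
    dplyr::mutate(ok = is.finite(.data$back_mean) &
                    abs(.data$back_mean - .data$nominal_conc_uM) <=
                      accuracy_tol * .data$nominal_conc_uM &
                    (is.na(.data$cv) | .data$cv <= cv_tol)) |>
    dplyr::summarise(
      loq_uM = if (any(.data$ok)) min(.data$nominal_conc_uM[.data$ok])
               else Inf,
      .groups = "drop")
  out <- dplyr::left_join(curves, loq, by = "analyte") |>
    dplyr::mutate(quantifiable = is.finite(.data$loq_uM) & .data$usable)
  structure(out, class = class(curves))
}

#' Fit calibration curves and LOQs in one step
#'
#' @inheritParams determine_loq
#' @return The joined calibration table (see [fit_calibration()] and
#'   [determine_loq()]).
#' @export
calibrate <- function(standards, accuracy_tol = 0.2, cv_tol = 0.2) {
  curves <- fit_calibration(standards)
  determine_loq(standards, curves, accuracy_tol, cv_tol)
}

#' @export
tidy.calibration_curves <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.calibration_curves <- function(x, ...) {
  tibble::tibble(n_analytes = nrow(x),
                 n_quantifiable = sum(x$quantifiable %||% x$usable),
                 median_r2 = stats::median(x$r2, na.rm = TRUE))
}

#' Quantify one analyte in one cell well
#'
#' Inverts the measurement chain: back-calculate the analysis-solution
#' concentration from the calibration line, censor below LOQ, convert to the
#' amount in the measured aliquot (`conc_uM * aliquot_volume_uL * 1000` fmol),
#' multiply by `split_factor` because only half the lysate was analyzed, and
#' divide by the spherical cell volume `V = (pi/6) d^3` (um^3 = fL) to obtain
#' the intracellular concentration in uM.
#'
#' @param area Peak area for this analyte/well.
#' @param curve One-row calibration tibble for the analyte (with `loq_uM`).
#' @param well One-row well tibble; must be a single-cell well with a
#'   diameter.
#' @param aliquot_volume_uL Analysis-solution volume represented by the
#'   measured aliquot (default 4).
#' @param split_factor Lysate split correction (default 2: the measured half
#'   is doubled).
#' @return A one-row tibble: `analyte`, `well_id`, `area`,
#'   `analysis_conc_uM`, `amount_fmol`, `cell_volume_pL`, `conc_uM`,
#'   `below_loq`. Negative back-calculated concentrations are clamped to 0
#'   and censored.
#' @export
quantify_cell <- function(area, curve, well, aliquot_volume_uL = 4,
                          split_factor = 2) {
  if (well$status != "single") {
    stop("quantification is defined for single-cell wells only (well ",
         well$well_id, " is ", well$status, ")", call. = FALSE)
  }
  if (is.na(well$diameter_um)) {
    stop("well ", well$well_id, " has no measured diameter", call. = FALSE)
  }
  if (!isTRUE(curve$usable)) {
    stop("calibration curve for ", curve$analyte, " is not usable",
         call. = FALSE)
  }
  analysis_conc <- max(0, (area - curve$intercept) / curve$slope)
  below <- analysis_conc < curve$loq_uM
  v_fl <- pi / 6 * well$diameter_um^3
  amount_fmol <- if (below) 0 else {
    split_factor * analysis_conc * aliquot_volume_uL * 1e3
  }
  conc <- if (below) 0 else amount_fmol / v_fl * 1e6  # fmol/fL = M; *1e6 = uM
  tibble::tibble(analyte = curve$analyte, well_id = well$well_id,
                 area = area, analysis_conc_uM = analysis_conc,
                 amount_fmol = amount_fmol, cell_volume_pL = v_fl / 1e3,
                 conc_uM = conc, below_loq = below)
}

#' Quantify a peak-area matrix over all single-cell wells
#'
#' Vectorized [quantify_cell()] over every (analyte, single well) pair.
#'
#' @param peak_areas Analyte x well matrix of areas.
#' @param curves Calibration table from [calibrate()].
#' @param wells Well metadata tibble.
#' @inheritParams quantify_cell
#' @return A tibble of quantification results, one row per analyte/cell.
#' @export
quantify_wells <- function(peak_areas, curves, wells, aliquot_volume_uL = 4,
                           split_factor = 2) {
  singles <- dplyr::filter(wells, .data$status == "single",
                           .data$well_id %in% colnames(peak_areas))
  usable <- dplyr::filter(curves, .data$usable)
  res <- tidyr::expand_grid(analyte = usable$analyte,
                            well_id = singles$well_id) |>
    dplyr::left_join(usable, by = "analyte") |>
    dplyr::left_join(dplyr::select(singles, "well_id", "diameter_um",
                                   "batch"),
                     by = "well_id") |>
    dplyr::mutate(
      area = peak_areas[cbind(.data$analyte, .data$well_id)],
      analysis_conc_uM = pmax(0, (.data$area - .data$intercept) /
                                .data$slope),
      below_loq = .data$analysis_conc_uM < .data$loq_uM,
      cell_volume_pL = pi / 6 * .data$diameter_um^3 / 1e3,
      amount_fmol = ifelse(.data$below_loq, 0,
                           split_factor * .data$analysis_conc_uM *
                             aliquot_volume_uL * 1e3),
      conc_uM = ifelse(.data$below_loq, 0,
                       .data$amount_fmol / (.data$cell_volume_pL * 1e-3))) |>
    dplyr::select("analyte", "well_id", "batch", "area",
                  "analysis_conc_uM", "amount_fmol", "cell_volume_pL",
                  "conc_uM", "below_loq")
  inform_stage("quantify_wells", sprintf(
    "%d analytes x %d single wells; %.1f%% below LOQ",
    nrow(usable), nrow(singles), 100 * mean(res$below_loq)))
  res
}

#' Assemble quantification results into a metabolite matrix
#'
#' @param results Tibble from [quantify_wells()] (or rows of
#'   [quantify_cell()]).
#' @param wells Well metadata tibble; only single wells enter the matrix.
#' @return A [metabolite_matrix] (analytes x single cells), below-LOQ entries
#'   0 with mask `TRUE`.
#' @export
assemble_metabolite_matrix <- function(results, wells) {
  singles <- wells$well_id[wells$status == "single"]
  unknown <- setdiff(results$well_id, wells$well_id)
  if (length(unknown) > 0) {
    stop("results reference unknown well(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(results[c("analyte", "well_id")])) {
    stop("duplicate (analyte, well) results", call. = FALSE)
  }
  results <- dplyr::filter(results, .data$well_id %in% singles)
  analytes <- unique(results$analyte)
  cells <- intersect(singles, unique(results$well_id))
  conc <- matrix(0, length(analytes), length(cells),
                 dimnames = list(analytes, cells))
  mask <- matrix(TRUE, length(analytes), length(cells),
                 dimnames = list(analytes, cells))
  conc[cbind(results$analyte, results$well_id)] <- results$conc_uM
  mask[cbind(results$analyte, results$well_id)] <- results$below_loq
  batch <- stats::setNames(wells$batch[match(cells, wells$well_id)], cells)
  metabolite_matrix(conc, mask, batch)
}

#' Empty-well background report
#'
#' Back-calculates analysis-solution concentrations for wells in which no
#' cell was dispensed, to check for metabolite leakage or carry-over: counts,
#' per analyte, the empty wells whose signal exceeds the LOQ.
#'
#' @param peak_areas Analyte x well area matrix (must include empty wells).
#' @param curves Calibration table with LOQs.
#' @param wells Well metadata tibble.
#' @return Tibble: `analyte`, `n_empty`, `n_detected`,
#'   `median_analysis_conc_uM` (median over detected wells; `NA` if none).
#' @export
background_report <- function(peak_areas, curves, wells) {
  empties <- wells$well_id[wells$status == "empty"]
  empties <- intersect(empties, colnames(peak_areas))
  if (length(empties) == 0) {
    warning("no empty wells to assess", call. = FALSE)
    return(tibble::tibble(analyte = character(), n_empty = integer(),
                          n_detected = integer(),
                          median_analysis_conc_uM = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(curves)), function(i) {
    cv <- curves[i, ]
    if (!(cv$analyte %in% rownames(peak_areas))) return(NULL)
    bc <- pmax(0, (peak_areas[cv$analyte, empties] - cv$intercept) / cv$slope)
    det <- bc >= cv$loq_uM
    tibble::tibble(analyte = cv$analyte, n_empty = length(empties),
                   n_detected = sum(det),
                   median_analysis_conc_uM =
                     if (any(det)) stats::median(bc[det]) else NA_real_)
  })
}
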