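#' Default targeted-analyte panel for the plate simulator
#'
#' Twelve analytes shaped like a monoterpene indole alkaloid panel in a
#' medicinal-plant leaf: idioblast-stored alkaloids spanning low uM to tens of
#' mM, an epidermal seco-iridoid plus a flavonoid restricted to one epidermal
#' subtype, and two transported compounds whose biosynthesis genes sit in a
#' cell population different from (or much rarer than) the accumulating one.
#'
#' Roles: `in_situ` analytes accumulate in the cells that express their
#' biosynthesis genes (expression follows a unimodal function of the cell's
#' own concentration); `transported` analytes accumulate away from their
#' source cells; `ubiquitous` analytes appear sporadically everywhere.
#'
#' @return A tibble with list-columns `accum_types`, `genes`, `source_types`.
#' @export
default_analytes <- function() {
  epi <- c("epidermis_A", "epidermis_B")
  all_types <- c(epi, "idioblast", "ipap", "parenchyma")
  tibble::tibble(
    analyte = c("vindoline", "deacetylvindoline", "anhydrovinblastine",
                "serpentine", "ajmalicine", "vindolinine", "vindorosine",
                "secologanin", "mauritianin", "catharanthine", "loganic_acid",
                "strictosidine"),
    role = c(rep("in_situ", 9), "transported", "transported", "ubiquitous"),
    accum_types = list("idioblast", "idioblast", "idioblast", "idioblast",
                       "idioblast", "idioblast", "idioblast", epi,
                       "epidermis_B", "idioblast", "parenchyma", all_types),
    accum_frac = c(rep(1, 10), 0.12, 0.1),
    log10_mean = c(4.7, 1.0, 1.5, 2.5, 2.0, 1.8, 2.3, 2.7, 2.2, 4.0, 4.6, 0.5),
    log10_sd = c(0.5, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.35, 0.3, 0.5, 0.3, 0.4),
    genes = list(c("NMT", "D4H", "DAT"), character(), "PRX1", character(),
                 character(), character(), character(), c("LAMT", "SLS"),
                 "FLS1", c("CS", "TDC"), c("G8H", "ISY"), character()),
    source_types = list("idioblast", "idioblast", "idioblast", "idioblast",
                        "idioblast", "idioblast", "idioblast", epi,
                        "epidermis_B", epi, "ipap", all_types),
    source_frac = c(rep(1, 9), 0.15, 1, 1),
    calib_slope = 1e7 * c(1.0, 0.7, 0.9, 1.2, 1.1, 0.8, 1.3, 1.5, 0.6, 1.4,
                          1.6, 1.05),
    calib_intercept = rep(0, 12)
  )
}

#' Simulation configuration for synthetic multiplexed plates
#'
#' Defaults emulate a four-plate, 96-well study of leaf protoplasts: two
#' collection batches, roughly a quarter of wells empty and a few percent
#' doublets, five cell types with IPAP (internal phloem-associated
#' parenchyma) held below 4% of cells, 2,000 genes, and the 12-analyte panel
#' of [default_analytes()] with external-calibration chemistry.
#'
#' @param n_plates,wells_per_plate Plate layout.
#' @param frac_empty,frac_doublet Proportions of empty and doublet wells.
#' @param cell_type_props Named proportions over the five cell types; must
#'   sum to 1.
#' @param n_genes Total genes, including markers/biosynthesis/enriched genes.
#' @param n_enriched_per_type Type-enriched background genes per cell type.
#' @param nb_dispersion Negative-binomial size (shape) parameter; variance is
#'   `mu + mu^2 / nb_dispersion`, so `Inf` gives Poisson counts.
#' @param depth_mean Expected total counts for a library-size factor of 1.
#' @param lib_sdlog Log-sd of the log-normal library-size factor.
#' @param diameter_range_um Uniform range of protoplast diameters.
#' @param analytes Analyte panel tibble, see [default_analytes()].
#' @param trend_a Amplitude of the unimodal concentration-expression link.
#' @param calib_ladder_rel Dilution ladder of the calibration series as
#'   multiples of each analyte's expected median analysis-solution
#'   concentration (standards are diluted to bracket the expected sample
#'   range); measured in triplicate.
#' @param calib_cv Proportional coefficient of variation of peak areas.
#' @param calib_sd_add Additive area noise floor.
#' @param area_floor Instrument floor: areas below it are recorded as 0.
#' @param aliquot_volume_uL Volume of analysis solution represented by one
#'   measured aliquot; half of each lysate is analyzed.
#' @param split_factor Lysate split (2 = measured half is doubled).
#' @param trace_rate Probability that an empty well shows a trace of an
#'   abundant analyte (medium background).
#' @param trace_analysis_rel Analysis-solution concentration of such traces,
#'   as a fraction of the analyte's expected median cell signal (small
#'   against real cells, but above the quantification limit).
#' @param trace_analytes Analytes eligible for trace background.
#' @param batch_scale Per-batch multiplicative offsets on metabolite pools.
#' @param marker_mean,source_mean,enrich_fold,de_high,de_low Expression-model
#'   constants (marker/source-gene means, fold enrichment, and the two
#'   epidermal-subtype means for the designed differentially expressed genes).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_plates = 4, wells_per_plate = 96,
                       frac_empty = 0.24, frac_doublet = 0.03,
                       cell_type_props = c(epidermis_A = 0.34,
                                           epidermis_B = 0.22,
                                           idioblast = 0.08,
                                           ipap = 0.03,
                                           parenchyma = 0.33),
                       n_genes = 2000, n_enriched_per_type = 8,
                       nb_dispersion = 2, depth_mean = 8000,
                       lib_sdlog = 0.8,
                       diameter_range_um = c(20, 60),
                       analytes = default_analytes(),
                       trend_a = 80,
                       calib_ladder_rel = 10^seq(-2.5, 1.5,
                                                 length.out = 7),
                       calib_cv = 0.05, calib_sd_add = 0,
                       area_floor = 1,
                       aliquot_volume_uL = 4, split_factor = 2,
                       trace_rate = 0.05, trace_analysis_rel = 0.5,
                       trace_analytes = c("vindoline", "catharanthine",
                                          "loganic_acid", "secologanin"),
                       batch_scale = c(1, 1.15),
                       marker_mean = 30, source_mean = 25, enrich_fold = 12,
                       de_high = 20, de_low = 4,
                       seed = 1L) {
  if (abs(sum(cell_type_props) - 1) > 1e-9) {
    stop("cell_type_props must sum to 1", call. = FALSE)
  }
  if (any(cell_type_props < 0)) stop("proportions must be non-negative",
                                     call. = FALSE)
  if (frac_empty < 0 || frac_doublet < 0 || frac_empty + frac_doublet > 1) {
    stop("frac_empty/frac_doublet must be valid proportions", call. = FALSE)
  }
  if (any(analytes$log10_sd < 0)) stop("log10_sd must be >= 0", call. = FALSE)
  if (seed != as.integer(seed)) stop("seed must be an integer", call. = FALSE)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Internal: the designed gene universe for a config.
sim_genes <- function(cfg) {
  special <- c("NLTP2", "CB21", "D4H", "DAT", "NMT", "PRX1", "G8H", "ISY",
               "LAMT", "SLS", "FLS1", "CS", "TDC", "KCS1", "LTP3", "LTP5")
  types <- names(cfg$cell_type_props)
  enriched <- unlist(lapply(types, function(t) {
    sprintf("ENR_%s_%02d", t, seq_len(cfg$n_enriched_per_type))
  }))
  n_filler <- cfg$n_genes - length(special) - length(enriched)
  if (n_filler < 0) stop("n_genes too small for the designed gene sets",
                         call. = FALSE)
  c(special, enriched, sprintf("G%04d", seq_len(n_filler)))
}

# Internal: marker-gene map used by the generator and the default rules.
sim_marker_map <- function() {
  list(idioblast = c("D4H", "DAT"), ipap = c("G8H", "ISY"),
       epidermis_A = c("NLTP2", "CB21"), epidermis_B = c("NLTP2", "CB21"))
}

#' Unimodal concentration-expression link
#'
#' Expression of an in-situ biosynthesis gene rises with its product's
#' intracellular concentration, peaks, then declines slightly at very high
#' pools (a storage-phase pattern):
#' `g(c) = a * log10(1 + c / c0) * exp(-c / c1)`.
#'
#' @param conc_uM Concentrations (uM).
#' @param a Amplitude (expected counts at the plateau).
#' @param c0 Half-rise scale (uM).
#' @param c1 Decline scale (uM).
#' @return Expected expression, same length as `conc_uM`.
#' @export
trend_link <- function(conc_uM, a = 80, c0 = 5000, c1 = 350000) {
  a * log10(1 + conc_uM / c0) * exp(-conc_uM / c1)
}

#' Expected analysis-solution concentration for an intracellular pool
#'
#' The forward measurement chain maps an intracellular concentration to the
#' analysis solution: a reference-diameter sphere's volume, halved by the
#' lysate split, diluted into the aliquot volume. Used to position each
#' analyte's calibration ladder around its expected sample range.
#'
#' @param log10_conc_uM log10 of the intracellular concentration (uM).
#' @param cfg A [sim_config()].
#' @return Analysis-solution concentration in uM.
#' @export
expected_analysis_conc <- function(log10_conc_uM, cfg) {
  d_ref <- mean(cfg$diameter_range_um)
  v_fl <- pi / 6 * d_ref^3
  10^log10_conc_uM * v_fl * 1e-6 / cfg$split_factor /
    (cfg$aliquot_volume_uL * 1e3)
}

#' Concentration at which the unimodal link peaks
#'
#' Solved numerically over the positive axis.
#'
#' @inheritParams trend_link
#' @param upper Search upper bound (uM).
#' @return Peak concentration in uM.
#' @export
trend_peak <- function(a = 80, c0 = 5000, c1 = 350000, upper = 1e8) {
  stats::optimize(function(c) trend_link(c, a, c0, c1),
                  interval = c(c0 * 1e-3, upper), maximum = TRUE)$maximum
}

# Internal: per-analyte link scales derived from its concentration regime.
analyte_link_scales <- function(log10_mean) {
  list(c0 = 10^(log10_mean - 1), c1 = 10^(log10_mean + 0.85))
}

#' Simulate plate wells with ground-truth cell types
#'
#' Draws well statuses (single/doublet/empty), protoplast diameters, batches
#' (plates are collected on two alternating days) and true cell types.
#'
#' @param cfg A [sim_config()].
#' @return A list with `wells` (tibble: well_id, plate, batch, status,
#'   diameter_um) and `truth` (tibble: well_id, true_type, plus doublet
#'   component types). Empty wells have `true_type = "none"`.
#' @export
simulate_wells <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_plates * cfg$wells_per_plate
  plate <- rep(sprintf("P%d", seq_len(cfg$n_plates)),
               each = cfg$wells_per_plate)
  batch <- sprintf("day%d", ((match(plate, unique(plate)) - 1) %% 2) + 1)
  n_col <- ceiling(cfg$wells_per_plate / 8)
  pos <- sprintf("%s%02d",
                 rep(LETTERS[1:8], times = n_col)[seq_len(cfg$wells_per_plate)],
                 rep(seq_len(n_col), each = 8)[seq_len(cfg$wells_per_plate)])
  well_id <- paste0(plate, "-",
                    rep(pos[seq_len(cfg$wells_per_plate)], cfg$n_plates))
  status <- sample(c("empty", "doublet", "single"), n, replace = TRUE,
                   prob = c(cfg$frac_empty, cfg$frac_doublet,
                            1 - cfg$frac_empty - cfg$frac_doublet))
  diameter <- ifelse(status == "empty", NA_real_,
                     stats::runif(n, cfg$diameter_range_um[1],
                                  cfg$diameter_range_um[2]))
  types <- names(cfg$cell_type_props)
  true_type <- rep("none", n)
  nonempty <- status != "empty"
  true_type[nonempty] <- sample(types, sum(nonempty), replace = TRUE,
                                prob = cfg$cell_type_props)
  comp2 <- rep(NA_character_, n)
  is_dbl <- status == "doublet"
  comp2[is_dbl] <- sample(types, sum(is_dbl), replace = TRUE,
                          prob = cfg$cell_type_props)
  wells <- tibble::tibble(well_id = well_id, plate = plate, batch = batch,
                          status = status, diameter_um = diameter)
  truth <- tibble::tibble(well_id = well_id, true_type = true_type,
                          doublet_type2 = comp2)
  inform_stage("simulate_wells", sprintf(
    "%d wells: %d single / %d doublet / %d empty; seed %d", n,
    sum(status == "single"), sum(is_dbl), sum(status == "empty"), cfg$seed))
  list(wells = validate_wells(wells), truth = truth)
}

# Internal: expected-count matrix (genes x non-empty profiles) for given
# types and true metabolite concentrations. conc may be NULL (no link genes
# resolved yet); lib are per-profile library factors.
sim_mean_matrix <- function(genes, types_of_cell, conc, cfg, base_mean) {
  n_cells <- length(types_of_cell)
  M <- matrix(base_mean, nrow = length(genes), ncol = n_cells,
              dimnames = list(genes, names(types_of_cell)))
  mm <- sim_marker_map()
  # markers: zero outside their type, fixed mean inside
  for (g in c("D4H", "DAT")) M[g, ] <- ifelse(types_of_cell == "idioblast",
                                              cfg$marker_mean, 0)
  for (g in c("G8H", "ISY")) M[g, ] <- ifelse(types_of_cell == "ipap",
                                              cfg$marker_mean, 0)
  for (g in c("NLTP2", "CB21")) {
    M[g, ] <- ifelse(types_of_cell %in% c("epidermis_A", "epidermis_B"),
                     cfg$marker_mean, 0)
  }
  # enriched background genes
  for (t in names(cfg$cell_type_props)) {
    gs <- sprintf("ENR_%s_%02d", t, seq_len(cfg$n_enriched_per_type))
    M[gs, ] <- sweep(M[gs, , drop = FALSE], 2,
                     ifelse(types_of_cell == t, cfg$enrich_fold, 1), `*`)
  }
  # designed epidermal-subtype DE genes
  for (g in c("KCS1", "LTP3", "LTP5")) {
    M[g, ] <- ifelse(types_of_cell == "epidermis_B", cfg$de_high, cfg$de_low)
  }
  an <- cfg$analytes
  for (i in seq_len(nrow(an))) {
    gs <- an$genes[[i]]
    if (length(gs) == 0) next
    if (an$role[i] == "in_situ") {
      sc <- analyte_link_scales(an$log10_mean[i])
      c_i <- conc[an$analyte[i], names(types_of_cell)]
      M[gs, ] <- rep(trend_link(c_i, cfg$trend_a, sc$c0, sc$c1),
                     each = length(gs))
    } else if (an$role[i] == "transported") {
      # expressed in (a fraction of) source-type cells, independent of where
      # the analyte accumulates; D4H/DAT/G8H/ISY already set above as markers
      own <- setdiff(gs, unlist(mm))
      if (length(own) > 0) {
        in_src <- types_of_cell %in% an$source_types[[i]]
        keep <- in_src & (src_subset_hash(names(types_of_cell), an$analyte[i])
                          < an$source_frac[i])
        M[own, ] <- rep(ifelse(keep, cfg$source_mean, 0), each = length(own))
      }
    }
  }
  M
}

# Internal: deterministic per-well uniform in [0,1) used to pick the sparse
# subset of source cells expressing a transported analyte's genes, stable
# across draws of the same wells.
src_subset_hash <- function(well_ids, analyte) {
  vapply(paste(well_ids, analyte), function(s) {
    h <- sum(utf8ToInt(s) * seq_along(utf8ToInt(s)) * 2654435761) %% 100000
    h / 100000
  }, numeric(1))
}

#' Simulate metabolite ground truth
#'
#' Draws true intracellular concentrations (uM): log-normal with
#' type-specific parameters for accumulating cells, exactly 0 elsewhere and
#' in empty wells; per-batch multiplicative scale offsets.
#'
#' @param sim Output of [simulate_wells()].
#' @param cfg The same [sim_config()].
#' @return A [metabolite_matrix] of true concentrations over all wells
#'   (empty wells are all-zero columns).
#' @export
simulate_metabolites <- function(sim, cfg) {
  set.seed(cfg$seed + 2L)
  wells <- sim$wells
  truth <- sim$truth
  an <- cfg$analytes
  n <- nrow(wells)
  conc <- matrix(0, nrow(an), n, dimnames = list(an$analyte, wells$well_id))
  batches <- unique(wells$batch)
  bscale <- rep(cfg$batch_scale, length.out = length(batches))
  names(bscale) <- batches
  for (i in seq_len(nrow(an))) {
    acc <- truth$true_type %in% an$accum_types[[i]] & wells$status != "empty"
    acc <- acc & stats::runif(n) < an$accum_frac[i]
    k <- sum(acc)
    if (k > 0) {
      conc[i, acc] <- 10^stats::rnorm(k, an$log10_mean[i], an$log10_sd[i]) *
        bscale[wells$batch[acc]]
    }
  }
  metabolite_matrix(conc, batch = stats::setNames(wells$batch, wells$well_id))
}

#' Simulate a gene-by-cell count matrix
#'
#' Negative-binomial counts with cell-type structure: marker genes are zero
#' outside their type, biosynthesis genes of in-situ analytes follow the
#' unimodal [trend_link()] of the cell's own true concentration, transported
#' analytes' genes are expressed in their source cells, doublet wells are
#' element-wise sums of two independent component draws, and empty wells are
#' all-zero.
#'
#' @param sim Output of [simulate_wells()].
#' @param cfg The [sim_config()].
#' @param met_true True concentrations from [simulate_metabolites()]; if
#'   `NULL` they are generated internally (same seed derivation).
#' @return An [expression_set] over all wells. Attributes: `true_means`
#'   (expected counts before library scaling), `doublet_parts` (list of the
#'   two component draws per doublet well), `de_genes` (the designed
#'   epidermal-subtype DE set).
#' @export
simulate_counts <- function(sim, cfg, met_true = NULL) {
  if (is.null(met_true)) met_true <- simulate_metabolites(sim, cfg)
  wells <- sim$wells
  truth <- sim$truth
  genes <- sim_genes(cfg)
  # gene lengths and baseline expression are annotation-like properties of
  # the gene universe: fixed across simulated experiments, not per seed
  set.seed(104729L)
  gl <- stats::setNames(pmax(200L, as.integer(round(
    stats::rlnorm(length(genes), log(1500), 0.5)))), genes)
  base_mean <- stats::rlnorm(length(genes), meanlog = log(2), sdlog = 1.2)
  set.seed(cfg$seed + 1L)
  n <- nrow(wells)
  counts <- matrix(0L, length(genes), n,
                   dimnames = list(genes, wells$well_id))
  lib <- stats::rlnorm(n, 0, cfg$lib_sdlog)

  nonempty <- which(wells$status != "empty")
  types1 <- stats::setNames(truth$true_type[nonempty],
                            wells$well_id[nonempty])
  M1 <- sim_mean_matrix(genes, types1, met_true$conc_uM, cfg, base_mean)
  scale1 <- cfg$depth_mean / colSums(M1)
  M1 <- sweep(M1, 2, scale1 * lib[nonempty], `*`)

  draw_nb <- function(mu) {
    if (is.infinite(cfg$nb_dispersion)) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion)
    }
  }
  counts[, nonempty] <- draw_nb(M1)

  # doublets: add an independent draw from the second component's profile;
  # its metabolite pools are drawn fresh (the well's recorded conc describes
  # the first component; doublets are excluded downstream anyway)
  doublet_parts <- list()
  dbl <- which(wells$status == "doublet")
  if (length(dbl) > 0) {
    types2 <- stats::setNames(truth$doublet_type2[dbl], wells$well_id[dbl])
    an <- cfg$analytes
    conc2 <- matrix(0, nrow(an), length(dbl),
                    dimnames = list(an$analyte, wells$well_id[dbl]))
    for (i in seq_len(nrow(an))) {
      acc <- types2 %in% an$accum_types[[i]] &
        stats::runif(length(dbl)) < an$accum_frac[i]
      if (any(acc)) {
        conc2[i, acc] <- 10^stats::rnorm(sum(acc), an$log10_mean[i],
                                         an$log10_sd[i])
      }
    }
    M2 <- sim_mean_matrix(genes, types2, conc2, cfg, base_mean)
    M2 <- sweep(M2, 2, cfg$depth_mean / colSums(M2) * lib[dbl], `*`)
    second <- matrix(draw_nb(M2), nrow = length(genes))
    for (j in seq_along(dbl)) {
      first <- counts[, dbl[j]]
      counts[, dbl[j]] <- first + second[, j]
      doublet_parts[[wells$well_id[dbl[j]]]] <-
        cbind(part1 = first, part2 = second[, j])
    }
  }

  es <- expression_set(counts, gl)
  attr(es, "true_means") <- M1
  attr(es, "doublet_parts") <- doublet_parts
  attr(es, "de_genes") <- c(
    "KCS1", "LTP3", "LTP5", "FLS1",
    sprintf("ENR_epidermis_A_%02d", seq_len(cfg$n_enriched_per_type)),
    sprintf("ENR_epidermis_B_%02d", seq_len(cfg$n_enriched_per_type)))
  inform_stage("simulate_counts", sprintf(
    "%d genes x %d wells; median depth %d", length(genes), n,
    as.integer(stats::median(colSums(counts[, nonempty])))))
  es
}

#' Simulate calibration standards and cell peak areas
#'
#' Applies the forward model that quantification must invert: the total
#' analyte amount in a cell of diameter d at concentration c is
#' `c * (pi/6) d^3` (uM x fL = 1e-6 fmol units); half of it is analyzed in
#' `aliquot_volume_uL` of solution; the peak area is linear in the
#' analysis-solution concentration with proportional noise `calib_cv` plus an
#' additive floor, and areas below `area_floor` are recorded as 0. Empty
#' wells show traces of abundant analytes at rate `trace_rate`.
#'
#' @param met_true True concentrations from [simulate_metabolites()].
#' @param wells Well tibble from [simulate_wells()].
#' @param cfg The [sim_config()].
#' @return A list: `standards` (tibble analyte, nominal_conc_uM, replicate,
#'   area) and `peak_areas` (analyte x well matrix).
#' @export
simulate_peak_areas <- function(met_true, wells, cfg) {
  set.seed(cfg$seed + 3L)
  an <- cfg$analytes
  noisy_area <- function(true_area) {
    sd <- cfg$calib_cv * true_area + cfg$calib_sd_add
    a <- true_area + stats::rnorm(length(true_area), 0, sd)
    a <- pmax(a, 0)
    a[a < cfg$area_floor] <- 0
    a
  }
  med <- expected_analysis_conc(an$log10_mean, cfg)
  standards <- tidyr::expand_grid(
    dplyr::tibble(analyte = an$analyte, med_analysis = med),
    ladder_rel = cfg$calib_ladder_rel,
    replicate = 1:3
  ) |>
    dplyr::mutate(nominal_conc_uM = .data$med_analysis * .data$ladder_rel) |>
    dplyr::left_join(
      dplyr::select(an, "analyte", "calib_slope", "calib_intercept"),
      by = "analyte") |>
    dplyr::mutate(
      area = noisy_area(.data$calib_slope * .data$nominal_conc_uM +
                          .data$calib_intercept)) |>
    dplyr::select("analyte", "nominal_conc_uM", "replicate", "area")

  d <- wells$diameter_um[match(colnames(met_true$conc_uM), wells$well_id)]
  v_fl <- ifelse(is.na(d), 0, pi / 6 * d^3)
  # uM * fL = 1e-6 fmol
  amount_fmol <- sweep(met_true$conc_uM, 2, v_fl * 1e-6, `*`)
  half_fmol <- amount_fmol / cfg$split_factor
  # 1 uM x 1 uL = 1000 fmol, so conc_uM = fmol / (uL * 1e3)
  analysis_conc <- half_fmol / (cfg$aliquot_volume_uL * 1e3)
  empty <- wells$status[match(colnames(met_true$conc_uM), wells$well_id)] ==
    "empty"
  if (any(empty) && cfg$trace_rate > 0) {
    tr <- which(rownames(analysis_conc) %in% cfg$trace_analytes)
    hit <- matrix(stats::runif(length(tr) * sum(empty)) < cfg$trace_rate,
                  nrow = length(tr))
    trace_level <- med[match(rownames(analysis_conc)[tr], an$analyte)] *
      cfg$trace_analysis_rel
    block <- analysis_conc[tr, empty, drop = FALSE]
    block[hit] <- (trace_level * array(1, dim(hit)))[hit]
    analysis_conc[tr, empty] <- block
  }
  true_area <- analysis_conc * an$calib_slope[match(rownames(analysis_conc),
                                                    an$analyte)] +
    an$calib_intercept[match(rownames(analysis_conc), an$analyte)]
  peak_areas <- matrix(noisy_area(true_area), nrow = nrow(true_area),
                       dimnames = dimnames(true_area))
  inform_stage("simulate_peak_areas", sprintf(
    "%d standards rows; %d x %d area matrix", nrow(standards),
    nrow(peak_areas), ncol(peak_areas)))
  list(standards = standards, peak_areas = peak_areas)
}

#' Run the full plate simulator
#'
#' @param cfg A [sim_config()].
#' @return A list: `wells`, `truth`, `expr` ([expression_set]), `met_true`
#'   ([metabolite_matrix] of true concentrations), `standards`,
#'   `peak_areas`, and the `cfg` used.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  sim <- simulate_wells(cfg)
  met_true <- simulate_metabolites(sim, cfg)
  expr <- simulate_counts(sim, cfg, met_true)
  pk <- simulate_peak_areas(met_true, sim$wells, cfg)
  list(wells = sim$wells, truth = sim$truth, expr = expr,
       met_true = met_true, standards = pk$standards,
       peak_areas = pk$peak_areas, cfg = cfg)
}

#' Write a simulated experiment to a directory
#'
#' Emits wells.tsv, counts.mtx (+ name sidecars), gene_lengths.tsv,
#' standards.csv, peak_areas.csv and truth.tsv.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(sim$wells, file.path(dir, "wells.tsv"), "tsv")
  write_expression_mtx(sim$expr, file.path(dir, "counts"))
  write_table(tibble::tibble(gene_id = names(sim$expr$gene_length_bp),
                             length_bp = unname(sim$expr$gene_length_bp)),
              file.path(dir, "gene_lengths.tsv"), "tsv")
  write_table(sim$standards, file.path(dir, "standards.csv"), "csv")
  write_table(sim$peak_areas, file.path(dir, "peak_areas.csv"),
              "csv", id_col = "analyte")
  write_table(sim$truth, file.path(dir, "truth.tsv"), "tsv")
  invisible(dir)
}
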