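# Shared fixtures, all built in code. Simulations are kept quiet.
options(scduet.verbose = FALSE)

# A small but structurally complete plate configuration for fast tests.
small_cfg <- function(seed = 1L, n_plates = 2, ...) {
  sim_config(n_plates = n_plates, wells_per_plate = 96, seed = seed, ...)
}

# A hand-built well tibble with n single wells of diameter d.
make_wells <- function(n, d = 40, status = "single", batch = "day1",
                       prefix = "W") {
  tibble::tibble(
    well_id = sprintf("%s%03d", prefix, seq_len(n)),
    plate = "P1", batch = batch, status = status,
    diameter_um = ifelse(status == "empty", NA_real_, d))
}

# A noiseless calibration ladder tibble for one analyte.
make_standards <- function(analyte = "A", slope = 100, intercept = 0,
                           concs = c(1, 10, 100), reps = 3) {
  tidyr::expand_grid(nominal_conc_uM = concs, replicate = seq_len(reps)) |>
    dplyr::mutate(analyte = analyte,
                  area = slope * nominal_conc_uM + intercept) |>
    dplyr::select(analyte, nominal_conc_uM, replicate, area)
}

# Run simulate -> calibrate -> quantify -> assemble on a config.
quantified_sim <- function(cfg) {
  sim <- simulate_experiment(cfg)
  cal <- calibrate(sim$standards)
  res <- quantify_wells(sim$peak_areas, cal, sim$wells,
                        aliquot_volume_uL = cfg$aliquot_volume_uL,
                        split_factor = cfg$split_factor)
  sim$met <- assemble_metabolite_matrix(res, sim$wells)
  sim$cal <- cal
  sim
}

# Full joined dataset from a config.
joined_sim <- function(cfg) {
  sim <- quantified_sim(cfg)
  qc <- qc_filter(sim$expr, sim$wells)
  sim$expr_norm <- suppressWarnings(normalize_expression(qc$expr))
  sim$ds <- join_by_well(sim$expr_norm, normalize_metabolites(sim$met),
                         sim$wells)
  sim
}

# Mean silhouette width of labelled points on 2-D coordinates.
mean_silhouette <- function(xy, labels) {
  d <- as.matrix(stats::dist(xy))
  s <- vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Brute-force Spearman with midranks: Pearson correlation of average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled ranks to group A (midranks for ties).
wilcoxon_enum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  na <- length(a)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  w_all <- apply(idx, 2, function(i) sum(r[i]) - na * (na + 1) / 2)
  mu <- mean(w_all)
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  min(1, p)
}
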