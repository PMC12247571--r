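#' Reference simulation parameter lists
#'
#' The parameter lattice explored by the full-scale simulation study:
#' coherence coefficients, phase differences (in units of pi/17), relative
#' amplitudes, and SNR mixing weights, with 20 active sources in each of the
#' randomized configurations and 350 observations.
#'
#' @return named list of parameter vectors
#' @export
reference_parameters <- function() {
  list(
    rho = c(0, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
    phi = c(0, 2, 4, 8, 16) / 17 * pi,
    a = c(0.5, 0.7, 0.8),
    snr_sigma = c(0.5, 0.6),
    n_sources = 20L,
    n_obs = 350L
  )
}

#' Default relative-threshold ladder (percent of N^2)
#'
#' The full ladder spans 5% down to 0.0005%. `detection_thresholds()` returns
#' the sub-ladder actually used for connection detection and hit scoring
#' (thresholds at and below 0.05%); the looser thresholds produce edge sets
#' whose clustering cost grows quadratically and contribute only to the
#' high-false-positive end of the FROC curve.
#'
#' @return numeric vector of threshold percentages, decreasing
#' @export
threshold_ladder <- function() {
  c(5, 1, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001, 0.0005)
}

#' @rdname threshold_ladder
#' @export
detection_thresholds <- function() {
  c(0.05, 0.01, 0.005, 0.001, 0.0005)
}

#' Assemble the forward workspace shared by all configurations
#'
#' Builds the sensor array, source grid, free-orientation spherical
#' leadfield, candidate-source screening, and the dipole distance matrix.
#'
#' @param n_channels number of sensors
#' @param sensor_radius sensor shell radius (m); the default 0.10 leaves a
#'   2 cm standoff above the 8 cm conductor, typical of a whole-head MEG
#'   helmet
#' @param conductor_radius conductor sphere radius (m)
#' @param spacing grid spacing (m); 0.008 reproduces the full-scale grid,
#'   0.012 the desk-scale grid
#' @param keep_fraction candidate screening fraction
#' @param seed seed for the sensor-array construction
#' @return list with `sensors`, `grid`, `lead` (free), `candidates`,
#'   `distances`
#' @export
setup_forward <- function(n_channels = 275L, sensor_radius = 0.10,
                          conductor_radius = 0.08, spacing = 0.012,
                          keep_fraction = 0.4, seed = 0L) {
  sensors <- build_sensor_array(n_channels, sensor_radius, seed = seed)
  grid <- build_source_grid(spacing, conductor_radius)
  lead <- sphere_leadfield(grid, sensors)
  candidates <- screen_candidate_sources(lead, keep_fraction)
  distances <- cross_dist(grid$positions, grid$positions)
  list(sensors = sensors, grid = grid, lead = lead,
       candidates = candidates, distances = distances)
}

# volume to threshold for one reconstruction method ------------------------

reconstruct_volume <- function(method, sim, setup, plan = NULL,
                               cond_guard = 1e6, trim = 0) {
  X <- sim$X
  csd <- sensor_csd(X)
  ci <- invert_csd(csd)
  oriented <- orient_leadfield(setup$lead, ci)
  if (method == "dual_subsampled") {
    if (is.null(plan)) stop("dual_subsampled needs a subsample plan", call. = FALSE)
    agg <- run_subsamples(X, oriented, plan, method = "dual",
                          distances = setup$distances, cond_guard = cond_guard,
                          trim = trim)
    return(list(values = agg$z, valid = agg$valid, aggregate = agg))
  }
  pair_method <- if (method == "dual") "dual" else "single"
  pr <- all_pairs_csd_power(oriented, ci, X = NULL, method = pair_method,
                            distances = setup$distances,
                            cond_guard = cond_guard)
  if (method == "imagcoh") {
    vol <- imag_coherency_map(pr)
    return(list(values = vol$values, valid = vol$valid))
  }
  coh <- coherence_volume(pr)
  nul <- null_coherence_volume(pr,
                               sigma = null_scales(pr,
                                                   distances = setup$distances,
                                                   trim = trim),
                               distances = setup$distances)
  cor <- corrected_map(coh, nul, mode = "subtract")
  list(values = cor$values, valid = cor$valid)
}

#' Run one simulated configuration through reconstruction and detection
#'
#' Simulates a sensor-level dataset, reconstructs the all-to-all connectivity
#' volume with each requested method, thresholds, clusters, classifies, and
#' scores against the designated (first two selected) dipoles. At `rho = 0`
#' the "hit" flag records near-pair false-positive occurrence for the
#' designated non-interacting pair.
#'
#' Methods: `"single"` (single-dipole beamformer, coherence minus null
#' coherence), `"dual"` (two-dipole beamformer, coherence minus null
#' coherence), `"imagcoh"` (single-dipole imaginary coherency), and
#' `"dual_subsampled"` (two-dipole beamformer with sensor subsampling,
#' thresholding the z-like aggregated map).
#'
#' @param setup a forward workspace from [setup_forward()]
#' @param rho,phi,a,snr_sigma simulation parameters
#' @param config_seed per-configuration master seed
#' @param methods subset of the four method names
#' @param plan `subsample_plan` for `dual_subsampled`
#' @param thresholds threshold ladder (percent of N^2)
#' @param n_sources,n_interacting,n_obs see [simulate_dataset()]
#' @param tolerance hit tolerance in meters
#' @param cond_guard pair condition guard
#' @param trim null-scale fit outlier trimming fraction, see
#'   [fit_null_scale()]; default 0 (off)
#' @param neighborhood per-endpoint 3-D adjacency used in 6-D clustering
#'   (6, 18, or 26); see [cluster_edges_6d()]
#' @return data frame, one row per method x threshold: `method`, `pct`,
#'   `hit`, `n_fp`, `n_connections`, plus the configuration parameters
#' @export
run_condition <- function(setup, rho, phi, a, snr_sigma, config_seed,
                          methods = c("dual_subsampled"),
                          plan = NULL,
                          thresholds = detection_thresholds(),
                          n_sources = 20L, n_interacting = 2L, n_obs = 350L,
                          tolerance = 0.02, cond_guard = 1e6, trim = 0,
                          neighborhood = 26) {
  sim <- simulate_dataset(setup$lead, setup$candidates, rho, phi, a,
                          snr_sigma, n_sources = n_sources,
                          n_interacting = n_interacting, n_obs = n_obs,
                          seed = config_seed)
  rows <- list()
  for (method in methods) {
    mplan <- plan
    if (!is.null(mplan)) mplan$seed <- derive_seed(config_seed, 23L)
    vol <- reconstruct_volume(method, sim, setup, plan = mplan,
                              cond_guard = cond_guard, trim = trim)
    for (pct in thresholds) {
      res <- tryCatch({
        es <- threshold_edges(vol$values, pct, valid = vol$valid)
        cl <- cluster_edges_6d(es, setup$grid, neighborhood = neighborhood)
        fc <- filter_clusters(cl, es, setup$grid)
        score_detection(fc$connections, sim$true_positions, setup$grid,
                        tolerance = tolerance)
      }, error = function(e) list(hit = NA, n_false_positives = NA_integer_,
                                  n_connections = NA_integer_))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, pct = pct,
        hit = res$hit, n_fp = res$n_false_positives,
        n_connections = res$n_connections,
        rho = rho, phi = phi, a = a, snr_sigma = snr_sigma,
        seed = config_seed)
    }
  }
  do.call(rbind, rows)
}

#' Run a set of randomized configurations for one parameter condition
#'
#' Repeats [run_condition()] over `n_configs` random source configurations,
#' drawing the phase difference per configuration from `phis` and deriving
#' per-configuration seeds from the master seed.
#'
#' @param setup forward workspace
#' @param n_configs number of random configurations
#' @param rho,a,snr_sigma condition parameters
#' @param phis pool of phase differences sampled per configuration
#' @param master_seed master seed for the whole condition
#' @param ... passed to [run_condition()]
#' @return stacked data frame of records with a `config` column
#' @export
run_configurations <- function(setup, n_configs, rho, a, snr_sigma,
                               phis = reference_parameters()$phi,
                               master_seed = 1L, ...) {
  recs <- vector("list", n_configs)
  phi_draw <- with_seed(derive_seed(master_seed, 29L),
                        sample(phis, n_configs, replace = TRUE))
  for (k in seq_len(n_configs)) {
    rec <- run_condition(setup, rho = rho, phi = phi_draw[k], a = a,
                         snr_sigma = snr_sigma,
                         config_seed = derive_seed(master_seed, 100L + k), ...)
    rec$config <- k
    recs[[k]] <- rec
  }
  do.call(rbind, recs)
}

#' Summarize detection records into hit rates
#'
#' A configuration counts as a hit for a method when at least one threshold
#' strictly below `hit_below` (percent) detected the designated pair.
#'
#' @param records data frame from [run_condition()]/[run_configurations()]
#' @param hit_below hit-rule threshold cut in percent (default 0.01)
#' @return data frame with `method`, `rho`, `phi`, `n_configs`, `hit_rate`
#' @export
summarize_hits <- function(records, hit_below = 0.01) {
  stopifnot(nrow(records) >= 1)
  if (!"config" %in% names(records)) records$config <- records$seed
  key <- interaction(records$method, records$rho, records$phi, records$config,
                     drop = TRUE)
  per_config <- do.call(rbind, lapply(split(records, key), function(s) {
    sel <- s$pct < hit_below
    data.frame(method = s$method[1], rho = s$rho[1], phi = s$phi[1],
               config = s$config[1],
               hit = any(s$hit[sel], na.rm = TRUE))
  }))
  key2 <- interaction(per_config$method, per_config$rho, per_config$phi,
                      drop = TRUE)
  out <- do.call(rbind, lapply(split(per_config, key2), function(s) {
    data.frame(method = s$method[1], rho = s$rho[1], phi = s$phi[1],
               n_configs = nrow(s), hit_rate = mean(s$hit))
  }))
  rownames(out) <- NULL
  out[order(out$method, out$rho, out$phi), , drop = FALSE]
}

#' Pooled hit rate across phases
#'
#' Fraction of configurations with a hit under the hit rule, pooled over all
#' phases and configurations in the records (for one method).
#'
#' @inheritParams summarize_hits
#' @param method method to pool
#' @return scalar hit rate in \[0, 1\]
#' @export
pooled_hit_rate <- function(records, method, hit_below = 0.01) {
  recs <- records[records$method == method, , drop = FALSE]
  stopifnot(nrow(recs) >= 1)
  if (!"config" %in% names(recs)) recs$config <- recs$seed
  hits <- vapply(split(recs, recs$config), function(s) {
    any(s$hit[s$pct < hit_below], na.rm = TRUE)
  }, logical(1))
  mean(hits)
}
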