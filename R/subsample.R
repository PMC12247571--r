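#' Sensor-array subsampling plan
#'
#' @param n_iterations number of subsample reconstructions (100 is the
#'   simulation-scale reference, 250 the real-data-scale reference; smaller
#'   desk-scale plans are routine)
#' @param channel_range integer (min, max) subset size; sizes are drawn
#'   uniformly on this range (50-150 of 275 is the simulation reference)
#' @param seed master seed; iteration draws derive from it
#' @return object of class `subsample_plan`
#' @export
subsample_plan <- function(n_iterations = 100L, channel_range = c(50L, 150L),
                           seed = 0L) {
  stopifnot(n_iterations >= 2, length(channel_range) == 2)
  channel_range <- as.integer(channel_range)
  if (channel_range[1] < 2 || channel_range[2] < channel_range[1]) {
    stop("channel_range must satisfy 2 <= min <= max", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 channel_range = channel_range,
                 seed = as.integer(seed)),
            class = "subsample_plan")
}

#' Draw one sensor subset
#'
#' Subset size uniform on the plan's range; channels drawn without
#' replacement. Reproducible from the plan's master seed plus the iteration
#' index.
#'
#' @param plan a `subsample_plan`
#' @param iteration iteration index (1-based)
#' @param n_total total number of channels available
#' @return sorted integer vector of channel indices
#' @export
draw_sensor_subset <- function(plan, iteration, n_total) {
  stopifnot(inherits(plan, "subsample_plan"))
  if (plan$channel_range[2] > n_total) {
    stop("channel_range exceeds the number of available channels", call. = FALSE)
  }
  with_seed(derive_seed(plan$seed, 1000L + iteration), {
    size <- sample(seq(plan$channel_range[1], plan$channel_range[2]), 1L)
    sort(sample.int(n_total, size))
  })
}

# streaming accumulator for per-iteration coherence/null volumes ------------

agg_init <- function(m) {
  z <- matrix(0, m, m)
  list(n = z, sum_coh = z, sum_null = z, sum_d = z, sum_d2 = z)
}

agg_update <- function(acc, coh_vals, null_vals, valid) {
  v <- valid & is.finite(coh_vals) & is.finite(null_vals)
  cv <- coh_vals; cv[!v] <- 0
  nv <- null_vals; nv[!v] <- 0
  d <- cv - nv
  acc$n <- acc$n + v
  acc$sum_coh <- acc$sum_coh + cv
  acc$sum_null <- acc$sum_null + nv
  acc$sum_d <- acc$sum_d + d
  acc$sum_d2 <- acc$sum_d2 + d^2
  acc
}

agg_final <- function(acc, grid, z_floor = 1e-12) {
  n <- acc$n
  valid <- n >= 2
  mean_coh <- ifelse(valid, acc$sum_coh / n, NA_real_)
  mean_null <- ifelse(valid, acc$sum_null / n, NA_real_)
  mean_d <- ifelse(valid, acc$sum_d / n, NA_real_)
  var_d <- ifelse(valid, (acc$sum_d2 - n * mean_d^2) / pmax(n - 1, 1), NA_real_)
  std_diff <- sqrt(pmax(var_d, 0))
  degenerate <- valid & std_diff <= z_floor
  z <- (mean_coh - mean_null) / pmax(std_diff, z_floor)
  z[!valid] <- NA_real_
  structure(list(mean_coherence = mean_coh, mean_null = mean_null,
                 std_difference = std_diff, z = z,
                 n_iterations_valid = n, valid = valid,
                 degenerate = degenerate, grid = grid),
            class = "subsample_aggregate")
}

#' Aggregate explicit lists of per-iteration volumes
#'
#' Convenience wrapper over the streaming accumulators used by
#' [run_subsamples()]; mainly useful for small problems and for checking the
#' aggregation arithmetic directly. The aggregate is invariant to the
#' ordering of the iterations.
#'
#' @param coh_list,null_list lists of equal-shape matrices (per iteration)
#' @param valid_list optional list of logical validity masks
#' @param grid the `source_grid` the volumes refer to (optional)
#' @param z_floor lower floor for the standard deviation in the z map
#' @return object of class `subsample_aggregate`: `mean_coherence`,
#'   `mean_null`, `std_difference` (sample sd of the per-iteration
#'   difference), `z`, per-pair valid-iteration counts
#' @export
aggregate_subsample_volumes <- function(coh_list, null_list, valid_list = NULL,
                                        grid = NULL, z_floor = 1e-12) {
  stopifnot(length(coh_list) == length(null_list), length(coh_list) >= 1)
  m <- nrow(as.matrix(coh_list[[1]]))
  acc <- agg_init(m)
  for (k in seq_along(coh_list)) {
    cv <- as.matrix(coh_list[[k]])
    nv <- as.matrix(null_list[[k]])
    v <- if (is.null(valid_list)) is.finite(cv) & is.finite(nv) else valid_list[[k]]
    acc <- agg_update(acc, cv, nv, v)
  }
  agg_final(acc, grid, z_floor)
}

#' Repeat the pairwise reconstruction over random sensor subsets
#'
#' For each iteration, draws a channel subset, forms the subsampled CSD from
#' the (fixed) data, inverts it without regularization, runs the all-pairs
#' two-dipole (or single-dipole) pipeline plus the null-coherence estimate,
#' and streams the per-iteration coherence and null volumes into across-
#' iteration means, the sample standard deviation of their difference, and
#' the z-like map `z = (mean coh - mean null) / max(sd, floor)`. The noise
#' realization is fixed: subsampling varies the channels, not the data.
#' Pairs invalid in an iteration are excluded from that iteration's
#' statistics; pairs with fewer than 2 valid iterations are marked invalid.
#'
#' By default dipole orientations are fixed once from the full-array CSD
#' (pass an oriented leadfield); set `orient_per_subsample = TRUE` and supply
#' a free-orientation leadfield to re-orient within every subset.
#'
#' @param X `sensor_spectra` or complex matrix (all channels x observations)
#' @param lead oriented `leadfield` (or free leadfield when
#'   `orient_per_subsample = TRUE`)
#' @param plan a `subsample_plan`
#' @param method `"dual"` (default) or `"single"`
#' @param distances optional precomputed dipole distance matrix
#' @param cond_guard pair condition guard, see [all_pairs_csd_power()]
#' @param orient_per_subsample recompute fixed orientations per subset
#' @param z_floor floor for the z denominator; floored pairs are flagged
#'   `degenerate`
#' @param trim per-seed fraction of largest-|cross| targets excluded from the
#'   null-scale fit (see [fit_null_scale()]); 0 (default) disables it
#' @return object of class `subsample_aggregate`
#' @export
run_subsamples <- function(X, lead, plan, method = "dual", distances = NULL,
                           cond_guard = 1e6, orient_per_subsample = FALSE,
                           z_floor = 1e-12, trim = 0) {
  stopifnot(inherits(plan, "subsample_plan"), inherits(lead, "leadfield"))
  Xm <- coef_of(X)
  n_total <- nrow(Xm)
  if (is.null(distances)) {
    distances <- cross_dist(lead$grid$positions, lead$grid$positions)
  }
  m <- lead$grid$n_dipoles
  spacing <- lead$grid$spacing
  acc <- agg_init(m)
  subsets <- vector("list", plan$n_iterations)
  for (it in seq_len(plan$n_iterations)) {
    idx <- draw_sensor_subset(plan, it, n_total)
    subsets[[it]] <- idx
    Xi <- Xm[idx, , drop = FALSE]
    ci <- invert_csd(sensor_csd(Xi))
    lead_i <- if (orient_per_subsample) {
      sub <- lead
      sub$gain <- lead$gain[idx, , drop = FALSE]
      orient_leadfield(sub, ci)
    } else {
      sub <- lead
      sub$gain <- lead$gain[idx, , drop = FALSE]
      sub
    }
    if (method == "dual") {
      # closed-form dual-pair maps straight from the Gram matrices
      H <- lead_i$gain
      A <- ci$inv %*% H
      G <- crossprod(Conj(H), A)
      G2 <- crossprod(Conj(A), A)
      km <- .dual_pair_maps(G, G2, lead_i$valid, distances, spacing,
                            cond_guard)
      sig <- null_scales_from_abs(km$abs_inner, km$abs_cross, km$valid,
                                  distances, spacing, trim = trim)
      smat <- (matrix(sig, m, m) + matrix(sig, m, m, byrow = TRUE)) / 2
      nul <- smat * km$abs_inner / km$sqrt_p
      acc <- agg_update(acc, km$coh, nul, km$valid)
    } else {
      pr <- all_pairs_csd_power(lead_i, ci, X = NULL, method = method,
                                distances = distances,
                                cond_guard = cond_guard)
      coh <- coherence(pr$cross, pr$p1, pr$p2)
      sig <- null_scales(pr, distances = distances, trim = trim)
      smat <- (matrix(sig, m, m) + matrix(sig, m, m, byrow = TRUE)) / 2
      nul <- smat * Mod(pr$inner) / sqrt(pr$p1 * pr$p2)
      acc <- agg_update(acc, coh, nul, pr$valid)
    }
  }
  out <- agg_final(acc, lead$grid, z_floor)
  out$subsets <- subsets
  out$plan <- plan
  out
}
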