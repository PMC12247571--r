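#' Coherence magnitude
#'
#' `|cross| / sqrt(p1 * p2)`; elementwise over scalars or matrices. Entries
#' with non-positive power become NA (missing-value marker).
#'
#' @param cross complex cross-spectrum
#' @param p1,p2 the two (non-negative) powers
#' @return real coherence magnitude in \[0, 1\]
#' @export
coherence <- function(cross, p1, p2) {
  out <- Mod(cross) / sqrt(p1 * p2)
  out[!is.finite(out) | p1 <= 0 | p2 <= 0] <- NA_real_
  out
}

#' All-pairs coherence volume
#'
#' The 6-dimensional coherence map (stored as a pairwise matrix over the 3-D
#' grid) computed from pairwise cross-spectra and powers.
#'
#' @param pairs a `pair_spectra` object
#' @return object of class `coherence_volume` with `values`, `valid`, `grid`
#' @export
coherence_volume <- function(pairs) {
  stopifnot(inherits(pairs, "pair_spectra"))
  vals <- coherence(pairs$cross, pairs$p1, pairs$p2)
  valid <- pairs$valid & is.finite(vals)
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid, grid = pairs$grid,
                 kind = "coherence"),
            class = "coherence_volume")
}

#' Imaginary-coherency volume (geometric-correction comparator)
#'
#' Magnitude of the imaginary part of the coherency, computed with
#' single-dipole filters. Discarding the real part removes instantaneous
#' (zero-lag) leakage at the cost of insensitivity to interactions with phase
#' differences near 0 or 180 degrees.
#'
#' @param pairs a `pair_spectra` from the single-dipole method
#' @return object of class `coherence_volume` (kind `imag_coherency`)
#' @export
imag_coherency_map <- function(pairs) {
  stopifnot(inherits(pairs, "pair_spectra"))
  coherency <- pairs$cross / sqrt(pairs$p1 * pairs$p2)
  vals <- abs(Im(coherency))
  valid <- pairs$valid & is.finite(vals)
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid, grid = pairs$grid,
                 kind = "imag_coherency"),
            class = "coherence_volume")
}

#' Fit the null-coherence scaling parameter for one seed dipole
#'
#' Least-squares slope through the origin of the absolute cross-spectrum on
#' the absolute filter inner product, over all valid target dipoles for the
#' seed. Strict proportionality is what the white-noise leakage model
#' predicts, so no intercept is fitted.
#'
#' @param cross_abs absolute cross-spectra of the seed against targets
#' @param inner_abs absolute filter inner products, same length
#' @param min_points minimum number of finite point pairs required
#' @param trim fraction of the largest `cross_abs` values excluded before
#'   fitting (robustness against contamination of the fit by genuine
#'   interactions, which appear as upward outliers); 0 disables trimming
#' @return the slope estimate (sigma-hat)
#' @export
fit_null_scale <- function(cross_abs, inner_abs, min_points = 10L, trim = 0) {
  ok <- is.finite(cross_abs) & is.finite(inner_abs)
  if (sum(ok) < min_points) {
    stop(sprintf("need at least %d valid target points to fit the null scale",
                 min_points), call. = FALSE)
  }
  if (trim > 0) {
    n_drop <- ceiling(trim * sum(ok))
    if (sum(ok) - n_drop >= min_points) {
      cut <- sort(cross_abs[ok], decreasing = TRUE)[n_drop]
      ok <- ok & cross_abs < cut
    }
  }
  den <- sum(inner_abs[ok]^2)
  if (den <= 0) stop("all filter inner products are zero for this seed",
                     call. = FALSE)
  sum(cross_abs[ok] * inner_abs[ok]) / den
}

#' Seed-wise null scales for a pairwise volume
#'
#' Vectorized application of [fit_null_scale()] to every seed dipole,
#' excluding the seed itself and targets within one grid spacing of the seed
#' (those are dominated by genuine seed blur rather than third-party noise
#' leakage). Seeds with fewer than `min_points` usable targets get NA.
#'
#' @param pairs a `pair_spectra`
#' @param distances optional precomputed distance matrix
#' @param min_points minimum usable targets per seed
#' @return numeric vector of per-seed scale estimates
#' @export
null_scales <- function(pairs, distances = NULL, min_points = 10L, trim = 0) {
  stopifnot(inherits(pairs, "pair_spectra"))
  if (is.null(distances)) {
    distances <- cross_dist(pairs$grid$positions, pairs$grid$positions)
  }
  null_scales_from_abs(Mod(pairs$inner), Mod(pairs$cross), pairs$valid,
                       distances, pairs$grid$spacing, min_points, trim)
}

# seed-wise origin-regression slopes from absolute inner products / cross
# spectra; shared by the public API and the fast subsampling path
null_scales_from_abs <- function(abs_inner, abs_cross, valid, distances,
                                 spacing, min_points = 10L, trim = 0) {
  use <- valid & is.finite(abs_inner) & is.finite(abs_cross) &
    (distances > spacing * (1 + 1e-9))
  if (trim > 0) {
    # drop the per-seed largest |cross| targets (possible true interactions)
    for (i in seq_len(nrow(use))) {
      row_ok <- which(use[i, ])
      n_drop <- ceiling(trim * length(row_ok))
      if (n_drop > 0 && length(row_ok) - n_drop >= min_points) {
        drop <- row_ok[order(abs_cross[i, row_ok],
                             decreasing = TRUE)[seq_len(n_drop)]]
        use[i, drop] <- FALSE
      }
    }
  }
  x <- abs_inner; x[!use] <- 0
  y <- abs_cross; y[!use] <- 0
  npts <- rowSums(use)
  den <- rowSums(x^2)
  num <- rowSums(x * y)
  ifelse(npts >= min_points & den > 0, num / den, NA_real_)
}

#' Null-coherence volume
#'
#' The expected leakage-driven coherence under no true interaction:
#' `null(i, j) = sigma(i) * |w_i . w_j| / sqrt(p_i * p_j)`, symmetrized by
#' averaging the two seed-wise evaluations (equivalently, using the mean of
#' the two seeds' scale estimates, since the inner-product magnitude and the
#' power product are symmetric).
#'
#' @param pairs a `pair_spectra`
#' @param sigma per-seed scales from [null_scales()]; computed when omitted
#' @param distances optional precomputed distance matrix
#' @return object of class `coherence_volume` (kind `null_coherence`)
#' @export
null_coherence_volume <- function(pairs, sigma = NULL, distances = NULL) {
  stopifnot(inherits(pairs, "pair_spectra"))
  if (is.null(sigma)) sigma <- null_scales(pairs, distances = distances)
  m <- nrow(pairs$cross)
  smat <- (matrix(sigma, m, m) + matrix(sigma, m, m, byrow = TRUE)) / 2
  vals <- smat * Mod(pairs$inner) / sqrt(pairs$p1 * pairs$p2)
  valid <- pairs$valid & is.finite(vals)
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid, grid = pairs$grid,
                 kind = "null_coherence", sigma = sigma),
            class = "coherence_volume")
}

#' Correct a coherence volume by its null-coherence estimate
#'
#' Either subtracts the null coherence (the simulation default) or divides by
#' it (the recommendation for real data, where averaging across subsamples
#' stabilizes the null estimate). In divide mode the denominator is floored
#' at `1e-6` times the median valid null value; floored entries are flagged
#' in the `floored` field.
#'
#' @param coh a `coherence_volume`
#' @param null a `coherence_volume` of kind `null_coherence`
#' @param mode `"subtract"` or `"divide"`
#' @return object of class `coherence_volume` (kind `corrected`)
#' @export
corrected_map <- function(coh, null, mode = c("subtract", "divide")) {
  mode <- match.arg(mode)
  stopifnot(inherits(coh, "coherence_volume"),
            inherits(null, "coherence_volume"),
            all(dim(coh$values) == dim(null$values)))
  valid <- coh$valid & null$valid
  floored <- NULL
  if (mode == "subtract") {
    vals <- coh$values - null$values
  } else {
    eps <- 1e-6 * stats::median(null$values[valid & null$values > 0])
    if (!is.finite(eps) || eps <= 0) eps <- 1e-12
    den <- pmax(null$values, eps)
    floored <- valid & (null$values < eps)
    vals <- coh$values / den
  }
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid, grid = coh$grid,
                 kind = "corrected", mode = mode, floored = floored),
            class = "coherence_volume")
}
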