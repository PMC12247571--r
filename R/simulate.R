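#' Parametrized source-level cross-spectral density matrix
#'
#' Constructs the Hermitian CSD `D A D` where
#' `D = diag(a, ..., a, 1-a, ..., 1-a)` assigns amplitude `a` to the first
#' `n_interacting` (coupled) sources and `1-a` to the remaining background
#' sources, and `A` is the identity except for the coupling entries
#' `rho * exp(+/- 1i * phi)` between the interacting sources (all pairwise
#' for `n_interacting > 2`). The population coherence between interacting
#' sources equals `rho` exactly, independent of `a` and `phi`, and the
#' interacting/background amplitude ratio is `a / (1 - a)`.
#'
#' @param rho coherence coefficient in \[0, 1\]
#' @param phi phase difference in radians
#' @param a relative amplitude in (0, 1)
#' @param n_sources total number of active sources
#' @param n_interacting number of mutually coupled sources (>= 2 for any
#'   coupling; all pairs among the first `n_interacting` share `rho`, `phi`)
#' @return complex Hermitian matrix of class `source_csd` with attributes
#'   `rho`, `phi`, `a`, `n_interacting`
#' @export
source_csd_matrix <- function(rho, phi, a, n_sources, n_interacting = 2L) {
  chk_num(rho, "rho"); chk_num(phi, "phi"); chk_num(a, "a")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1] (matrix not PSD otherwise)",
                               call. = FALSE)
  if (a <= 0 || a >= 1) stop("a must be in (0, 1)", call. = FALSE)
  if (n_interacting > n_sources) stop("n_interacting must not exceed n_sources",
                                      call. = FALSE)
  A <- diag(n_sources) + 0i
  if (n_interacting >= 2) {
    for (i in seq_len(n_interacting - 1)) {
      for (j in seq(i + 1, n_interacting)) {
        A[i, j] <- rho * exp(1i * phi)
        A[j, i] <- rho * exp(-1i * phi)
      }
    }
  }
  d <- c(rep(a, n_interacting), rep(1 - a, n_sources - n_interacting))
  M <- A * outer(d, d)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    stop("requested coupling structure is not positive semidefinite", call. = FALSE)
  }
  structure(M, class = c("source_csd", class(M)),
            rho = rho, phi = phi, a = a, n_interacting = as.integer(n_interacting))
}

# container for complex Fourier-coefficient matrices (channels/sources x obs)
sensor_spectra <- function(coefficients, role = c("signal", "noise", "mixed"),
                           level = c("sensor", "source")) {
  role <- match.arg(role)
  level <- match.arg(level)
  stopifnot(is.matrix(coefficients), ncol(coefficients) >= 1)
  structure(list(coefficients = coefficients, role = role, level = level),
            class = "sensor_spectra")
}

coef_of <- function(x) if (inherits(x, "sensor_spectra")) x$coefficients else x

#' Draw circularly-symmetric complex Gaussian observations
#'
#' Generates `n_obs` independent complex Gaussian vectors whose population
#' cross-spectral density equals `csd`, via the Hermitian matrix square root
#' applied to iid standard circular complex normals.
#'
#' @param csd Hermitian PSD matrix (e.g., from [source_csd_matrix()])
#' @param n_obs number of observations
#' @param seed integer seed; draws are deterministic per seed
#' @return a `sensor_spectra` (role `signal`, level `source`)
#' @export
draw_complex_gaussian <- function(csd, n_obs, seed = 0L) {
  M <- unclass(csd)
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1e-300)) {
    stop("csd must be positive semidefinite", call. = FALSE)
  }
  L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * Conj(t(e$vectors)))
  m <- nrow(M)
  Z <- with_seed(seed, {
    matrix(complex(real = stats::rnorm(m * n_obs),
                   imaginary = stats::rnorm(m * n_obs)) / sqrt(2), m, n_obs)
  })
  sensor_spectra(L %*% Z, role = "signal", level = "source")
}

#' Project source spectra to the sensor array
#'
#' Applies the generative model `Xs = H S` for the selected dipole columns of
#' an oriented leadfield (or a plain gain matrix with one column per source).
#'
#' @param lead an oriented `leadfield` (`n_ori == 1`) or a numeric gain matrix
#' @param sources a `sensor_spectra` (or matrix) of source Fourier coefficients
#' @param selection dipole indices, one per source row
#' @return a `sensor_spectra` (role `signal`, level `sensor`)
#' @export
mix_to_sensors <- function(lead, sources, selection) {
  H <- if (inherits(lead, "leadfield")) {
    if (lead$n_ori != 1L) {
      stop("leadfield must have fixed orientations resolved (n_ori == 1)",
           call. = FALSE)
    }
    lead$gain
  } else {
    lead
  }
  S <- coef_of(sources)
  if (length(selection) != nrow(S)) {
    stop("selection size must match the number of source rows", call. = FALSE)
  }
  if (max(selection) > ncol(H)) stop("selection out of range", call. = FALSE)
  sensor_spectra(H[, selection, drop = FALSE] %*% S,
                 role = "signal", level = "sensor")
}

#' Generate complex Gaussian sensor noise
#'
#' White circular complex Gaussian noise by default; optionally colored by a
#' supplied Hermitian PSD channel covariance (e.g., estimated from resting
#' data), in which case draws are premultiplied by its matrix square root.
#'
#' @param n_channels,n_obs matrix dimensions
#' @param seed integer seed
#' @param covariance optional channels x channels Hermitian PSD matrix
#' @return a `sensor_spectra` (role `noise`)
#' @export
generate_noise <- function(n_channels, n_obs, seed = 0L, covariance = NULL) {
  stopifnot(n_channels >= 1, n_obs >= 1)
  Z <- with_seed(seed, {
    matrix(complex(real = stats::rnorm(n_channels * n_obs),
                   imaginary = stats::rnorm(n_channels * n_obs)) / sqrt(2),
           n_channels, n_obs)
  })
  if (!is.null(covariance)) {
    stopifnot(nrow(covariance) == n_channels)
    e <- eigen(covariance, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1e-300)) {
      stop("noise covariance must be positive semidefinite", call. = FALSE)
    }
    L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * Conj(t(e$vectors)))
    Z <- L %*% Z
  }
  sensor_spectra(Z, role = "noise", level = "sensor")
}

# Frobenius norm of the cross-spectrum X X^H, via singular values of X
csd_frobenius <- function(X) sqrt(sum(svd(X, nu = 0, nv = 0)$d^4))

#' Combine signal and noise at a prescribed signal-to-noise mixing weight
#'
#' Each input is first rescaled so that the Frobenius norm of its
#' cross-spectrum `X X^H` equals 1, then mixed as
#' `X = sigma * Xs + (1 - sigma) * Xn`.
#'
#' @param Xs,Xn signal and noise `sensor_spectra` (or matrices) of equal shape
#' @param snr_sigma mixing weight in \[0, 1\]
#' @return a `sensor_spectra` (role `mixed`)
#' @export
combine_snr <- function(Xs, Xn, snr_sigma) {
  chk_num(snr_sigma, "snr_sigma")
  if (snr_sigma < 0 || snr_sigma > 1) stop("snr_sigma must be in [0, 1]",
                                           call. = FALSE)
  S <- coef_of(Xs); N <- coef_of(Xn)
  if (!all(dim(S) == dim(N))) stop("signal and noise shapes differ", call. = FALSE)
  fs <- csd_frobenius(S); fn <- csd_frobenius(N)
  if (fs == 0 || fn == 0) stop("zero-norm input cannot be SNR-scaled", call. = FALSE)
  sensor_spectra(snr_sigma * S / sqrt(fs) + (1 - snr_sigma) * N / sqrt(fn),
                 role = "mixed", level = "sensor")
}

#' Multitaper observation bookkeeping
#'
#' For a recording split into epochs and spectrally transformed with Slepian
#' tapers at the given half-bandwidth smoothing, the taper count per epoch is
#' `2 * epoch_length * smoothing - 1` and the total observation count is
#' `floor(record_length / epoch_length)` epochs times that.
#'
#' @param record_length total record duration in seconds
#' @param epoch_length epoch duration in seconds
#' @param smoothing spectral smoothing (half-bandwidth) in Hz
#' @return list with `n_tapers` and `n_obs`
#' @export
spectral_observation_count <- function(record_length, epoch_length, smoothing) {
  chk_num(record_length, "record_length")
  chk_num(epoch_length, "epoch_length")
  chk_num(smoothing, "smoothing")
  if (record_length <= 0 || epoch_length <= 0) {
    stop("durations must be positive", call. = FALSE)
  }
  if (smoothing * epoch_length < 1) {
    stop("smoothing too small for the epoch length (needs smoothing * epoch >= 1)",
         call. = FALSE)
  }
  n_tapers <- as.integer(floor(2 * epoch_length * smoothing - 1 + 1e-9))
  n_obs <- as.integer(floor(record_length / epoch_length + 1e-9)) * n_tapers
  list(n_tapers = n_tapers, n_obs = as.integer(n_obs))
}

# random tangential-dominant unit orientations for simulation dipoles
simulation_orientations <- function(grid, indices, seed = 0L,
                                    radial_weight = 0.2) {
  pos <- grid$positions[indices, , drop = FALSE]
  n <- nrow(pos)
  with_seed(derive_seed(seed, 7L), {
    u <- pos / pmax(row_norms(pos), 1e-12)
    v <- matrix(stats::rnorm(3 * n), n, 3)
    tang <- v - rowSums(v * u) * u
    tn <- row_norms(tang)
    # fall back to an arbitrary tangential direction for degenerate draws
    deg <- tn < 1e-9
    if (any(deg)) {
      tang[deg, ] <- cbind(-u[deg, 2], u[deg, 1], 0)
      tn[deg] <- row_norms(tang[deg, , drop = FALSE])
    }
    tang <- tang / tn
    q <- tang + radial_weight * stats::runif(n, -1, 1) * u
    q / row_norms(q)
  })
}

#' Simulate one sensor-level dataset
#'
#' Full generative chain for a single configuration: select `n_sources`
#' dipoles from the candidate set, assign random tangential-dominant
#' orientations, draw coupled source spectra from the parametrized CSD,
#' project them through the forward model, and mix with sensor noise at the
#' requested SNR weight. The first two (or `n_interacting`) selected dipoles
#' are the interacting pair.
#'
#' @param lead free-orientation `leadfield`
#' @param candidates candidate dipole indices (e.g., from
#'   [screen_candidate_sources()])
#' @param rho,phi,a,snr_sigma simulation parameters (see
#'   [source_csd_matrix()] and [combine_snr()])
#' @param n_sources,n_interacting source counts
#' @param n_obs number of observations
#' @param seed master seed for this configuration
#' @param noise_covariance optional colored-noise channel covariance
#' @return list with `X` (`sensor_spectra`, mixed), `selection`,
#'   `true_pair` (dipole indices), `true_positions` (2 x 3),
#'   `orientations`, and the parameters
#' @export
simulate_dataset <- function(lead, candidates, rho, phi, a, snr_sigma,
                             n_sources = 20L, n_interacting = 2L,
                             n_obs = 350L, seed = 0L,
                             noise_covariance = NULL) {
  stopifnot(inherits(lead, "leadfield"), lead$n_ori == 3L)
  if (length(candidates) < n_sources) {
    stop("not enough candidate dipoles for the requested source count",
         call. = FALSE)
  }
  selection <- with_seed(derive_seed(seed, 11L),
                         sample(candidates, n_sources))
  q <- simulation_orientations(lead$grid, selection, seed = seed)
  # oriented gain columns for the selected dipoles only
  H <- vapply(seq_along(selection), function(k) {
    cols <- 3L * (selection[k] - 1L) + 1:3
    lead$gain[, cols, drop = FALSE] %*% q[k, ]
  }, numeric(nrow(lead$gain)))
  csd <- source_csd_matrix(rho, phi, a, n_sources, n_interacting)
  S <- draw_complex_gaussian(csd, n_obs, seed = derive_seed(seed, 13L))
  Xs <- sensor_spectra(H %*% coef_of(S), role = "signal", level = "sensor")
  Xn <- generate_noise(nrow(H), n_obs, seed = derive_seed(seed, 17L),
                       covariance = noise_covariance)
  X <- combine_snr(Xs, Xn, snr_sigma)
  list(X = X, selection = selection,
       true_pair = selection[seq_len(max(2L, n_interacting))][1:2],
       true_positions = lead$grid$positions[selection[1:2], , drop = FALSE],
       orientations = q, rho = rho, phi = phi, a = a, snr_sigma = snr_sigma,
       n_obs = as.integer(n_obs), seed = as.integer(seed))
}
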