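#' Cross-spectral density of sensor Fourier coefficients
#'
#' `C = X X^H / n_obs`, Hermitian by construction.
#'
#' @param X a `sensor_spectra` or complex matrix (channels x observations)
#' @return complex Hermitian matrix
#' @export
sensor_csd <- function(X) {
  Xm <- coef_of(X)
  C <- tcrossprod(Xm, Conj(Xm)) / ncol(Xm)
  (C + Conj(t(C))) / 2
}

#' Invert a sensor CSD without regularization
#'
#' Exact inverse for full-rank matrices; Moore-Penrose pseudo-inverse with a
#' relative eigenvalue truncation otherwise (rank deficiency is routine when
#' the channel count approaches the observation count). An optional ridge
#' (diagonal loading, as a fraction of the mean sensor power) is exposed but
#' defaults to 0.
#'
#' @param csd complex Hermitian matrix
#' @param ridge diagonal loading fraction, default 0
#' @param tol relative eigenvalue truncation tolerance for the pseudo-inverse
#' @return object of class `csd_inverse` with fields `csd`, `inv`, `rank`
#' @export
invert_csd <- function(csd, ridge = 0, tol = 1e-10) {
  stopifnot(is.matrix(csd), nrow(csd) == ncol(csd))
  herm_err <- max(Mod(csd - Conj(t(csd))))
  if (herm_err > 1e-8 * max(Mod(csd), 1e-300)) {
    stop("csd is not Hermitian", call. = FALSE)
  }
  C <- (csd + Conj(t(csd))) / 2
  if (ridge > 0) {
    C <- C + ridge * mean(Re(diag(C))) * diag(nrow(C))
  }
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  keep <- vals > tol * max(vals, 0)
  if (!any(keep)) stop("csd has no positive spectrum", call. = FALSE)
  V <- e$vectors[, keep, drop = FALSE]
  inv <- V %*% ((1 / vals[keep]) * Conj(t(V)))
  inv <- (inv + Conj(t(inv))) / 2
  structure(list(csd = C, inv = inv, rank = sum(keep)), class = "csd_inverse")
}

inv_of <- function(x) if (inherits(x, "csd_inverse")) x$inv else x

#' Power-maximizing fixed orientation for one dipole
#'
#' Restricts the 3-column free-orientation gain to its numerically nonzero
#' column space (for a spherical conductor this removes the silent radial
#' direction), then picks the real unit orientation minimizing
#' `q' Re(H' C^-1 H) q`, i.e., maximizing the single-dipole beamformer output
#' power `1 / (h(q)' C^-1 h(q))`. The sign is fixed so the largest-magnitude
#' component of `q` is positive.
#'
#' @param H_free channels x 3 gain matrix
#' @param csd_inv a `csd_inverse` (or plain inverse matrix)
#' @param rank_tol relative eigenvalue tolerance on the 3x3 gain Gram used to
#'   identify the effective gain column space (silent directions sit at the
#'   numerical noise floor, many orders below this)
#' @return list with `orientation` (unit 3-vector) and `gain` (`H_free %*% q`)
#' @export
fixed_orientation <- function(H_free, csd_inv, rank_tol = 1e-8) {
  stopifnot(is.matrix(H_free), ncol(H_free) == 3)
  Ci <- inv_of(csd_inv)
  G0 <- crossprod(H_free)                       # 3x3 real Gram of the gain
  e0 <- eigen(G0, symmetric = TRUE)
  r <- sum(e0$values > rank_tol * max(e0$values, 0))
  if (r < 1) stop("degenerate gain (rank < 1)", call. = FALSE)
  V <- e0$vectors[, seq_len(r), drop = FALSE]
  G3 <- Re(crossprod(H_free, Ci %*% H_free))
  M <- crossprod(V, G3 %*% V)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  q <- drop(V %*% em$vectors[, r])
  q <- q / sqrt(sum(q^2))
  i <- which.max(abs(q))
  if (q[i] < 0) q <- -q
  list(orientation = q, gain = drop(H_free %*% q))
}

#' Fix orientations for all grid dipoles
#'
#' Applies [fixed_orientation()] per dipole (vectorized assembly of the
#' per-dipole 3x3 Gram matrices) and returns an oriented leadfield with one
#' column per dipole. By default the orientation is computed once from the
#' full-array CSD and reused across sensor subsamples.
#'
#' @param lead free-orientation `leadfield`
#' @param csd_inv full-array `csd_inverse`
#' @param rank_tol see [fixed_orientation()]
#' @return oriented `leadfield` (`n_ori == 1`) with `orientations` (m x 3)
#' @export
orient_leadfield <- function(lead, csd_inv, rank_tol = 1e-8) {
  stopifnot(inherits(lead, "leadfield"), lead$n_ori == 3L)
  Ci <- inv_of(csd_inv)
  H <- lead$gain
  m <- ncol(H) / 3L
  A <- Ci %*% H
  idx <- function(k) 3L * (seq_len(m) - 1L) + k
  # per-dipole 3x3 blocks of H'H and Re(H' Ci H), assembled entrywise
  G0 <- array(0, c(3, 3, m)); G3 <- array(0, c(3, 3, m))
  for (aa in 1:3) for (bb in 1:3) {
    G0[aa, bb, ] <- colSums(H[, idx(aa), drop = FALSE] * H[, idx(bb), drop = FALSE])
    G3[aa, bb, ] <- Re(colSums(Conj(H[, idx(aa), drop = FALSE]) *
                                 A[, idx(bb), drop = FALSE]))
  }
  gain <- matrix(0, nrow(H), m)
  orientations <- matrix(0, m, 3)
  valid <- lead$valid
  for (d in seq_len(m)) {
    if (!valid[d]) next
    g0 <- G0[, , d]
    e0 <- eigen((g0 + t(g0)) / 2, symmetric = TRUE)
    r <- sum(e0$values > rank_tol * max(e0$values, 0))
    if (r < 1) { valid[d] <- FALSE; next }
    V <- e0$vectors[, seq_len(r), drop = FALSE]
    M <- crossprod(V, G3[, , d] %*% V)
    em <- eigen((M + t(M)) / 2, symmetric = TRUE)
    q <- drop(V %*% em$vectors[, r])
    q <- q / sqrt(sum(q^2))
    i <- which.max(abs(q))
    if (q[i] < 0) q <- -q
    orientations[d, ] <- q
    gain[, d] <- H[, 3L * (d - 1L) + 1:3, drop = FALSE] %*% q
  }
  structure(list(
    gain = gain, n_ori = 1L, valid = valid, orientations = orientations,
    grid = lead$grid, sensors = lead$sensors, units = lead$units
  ), class = "leadfield")
}

#' Single-dipole unit-gain (LCMV/DICS) spatial filter
#'
#' `w' = (h' C^-1 h)^-1 h' C^-1`, satisfying the unit-gain constraint
#' `w' h = 1`.
#'
#' @param h gain vector (channels)
#' @param csd_inv a `csd_inverse` or inverse matrix
#' @param tol sensitivity guard: `h' C^-1 h` at or below this is an error
#' @return object of class `spatial_filter` with field `weights`
#'   (length-channels vector; the filter row `w'`)
#' @export
single_filter <- function(h, csd_inv, tol = 1e-300) {
  Ci <- inv_of(csd_inv)
  hc <- drop(Ci %*% h)
  den <- Re(sum(Conj(h) * hc))
  if (!is.finite(den) || den <= tol) {
    stop("insensitive location: h' C^-1 h is not positive", call. = FALSE)
  }
  structure(list(weights = Conj(hc) / den), class = "spatial_filter")
}

#' Two-dipole identity-gain spatial filter
#'
#' `W' = (H' C^-1 H)^-1 H' C^-1` with `H = [h1 h2]`, satisfying
#' `W' H = I_2`: each row passes its own dipole with unit gain while nulling
#' the other, cancelling mutual zero-lag leakage within the pair.
#'
#' @param h1,h2 gain vectors (must be linearly independent)
#' @param csd_inv a `csd_inverse` or inverse matrix
#' @param cond_guard maximum allowed condition number of the
#'   diagonally-normalized 2x2 pair Gram. The normalization makes the guard a
#'   pure collinearity test, insensitive to the (often orders-of-magnitude)
#'   depth-related scale difference between the two gain vectors:
#'   `cond = (1 + |c|) / (1 - |c|)` with `c` the metric correlation
#'   `g12 / sqrt(g11 g22)`.
#' @return object of class `pair_filter` with field `weights` (2 x channels;
#'   the stacked filter rows `W'`)
#' @export
pair_filter <- function(h1, h2, csd_inv, cond_guard = 1e6) {
  Ci <- inv_of(csd_inv)
  Hp <- cbind(h1, h2)
  B <- Ci %*% Hp
  Gp <- crossprod(Conj(Hp), B)
  Gp <- (Gp + Conj(t(Gp))) / 2
  g11 <- Re(Gp[1, 1]); g22 <- Re(Gp[2, 2])
  corr <- if (g11 > 0 && g22 > 0) Mod(Gp[1, 2]) / sqrt(g11 * g22) else Inf
  if (!is.finite(corr) || g11 <= 0 || g22 <= 0 ||
      (1 + corr) / max(1 - corr, .Machine$double.xmin) > cond_guard) {
    stop("near-collinear pair: normalized 2x2 Gram condition exceeds the guard",
         call. = FALSE)
  }
  Wt <- solve(Gp, Conj(t(B)))
  structure(list(weights = Wt), class = "pair_filter")
}

#' All-pairs two-dipole cross-spectra, powers, and filter inner products
#'
#' For every admissible dipole pair (i, j) of an oriented leadfield, computes
#' the quantities that the explicit two-dipole filter of [pair_filter()]
#' would produce: the pair cross-spectrum, the two within-pair powers, and
#' the Hermitian inner product of the two filter rows (which drives the
#' null-coherence estimate). The computation is fully vectorized through the
#' Gram matrices `G = H' C^-1 H` and `G2 = H' C^-2 H`; results are identical
#' to a naive per-pair loop.
#'
#' If `X` is supplied, source projections use the data directly
#' (`Q = (H'C^-1 X)(H'C^-1 X)^H / n`); if omitted, the algebraic identity
#' `C^-1 C C^-1 = C^-1` (which holds for the exact and the Moore-Penrose
#' inverse alike) gives `Q = G` and the data matrix is not needed.
#'
#' Pairs are excluded (NA, `valid = FALSE`) when the 2x2 pair Gram condition
#' number exceeds `cond_guard`, when the dipole distance is below one grid
#' spacing, on the diagonal, or when either dipole is invalid.
#'
#' @param lead oriented `leadfield`
#' @param csd_inv `csd_inverse` of the (subsampled) sensor CSD
#' @param X optional `sensor_spectra`/matrix of the same channels
#' @param method `"dual"` for two-dipole pair filters, `"single"` for
#'   ordinary single-dipole filters (the comparator pipelines)
#' @param distances optional precomputed m x m dipole distance matrix
#' @param cond_guard pair condition-number guard (dual method)
#' @param min_distance minimum dipole separation; defaults to the grid spacing
#' @return object of class `pair_spectra`: complex `cross`, real `p1`, `p2`,
#'   complex `inner`, logical `valid`, plus `method` and the grid
#' @export
all_pairs_csd_power <- function(lead, csd_inv, X = NULL,
                                method = c("dual", "single"),
                                distances = NULL, cond_guard = 1e6,
                                min_distance = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(lead, "leadfield"), lead$n_ori == 1L)
  Ci <- inv_of(csd_inv)
  H <- lead$gain
  m <- ncol(H)
  A <- Ci %*% H                                  # C^-1 H (channels x m)
  G <- crossprod(Conj(H), A)                     # H' C^-1 H
  G <- (G + Conj(t(G))) / 2
  G2 <- crossprod(Conj(A), A)                    # H' C^-2 H
  G2 <- (G2 + Conj(t(G2))) / 2
  if (is.null(X)) {
    Q <- G
  } else {
    Xm <- coef_of(X)
    P <- crossprod(Conj(A), Xm)                  # H' C^-1 X
    Q <- tcrossprod(P, Conj(P)) / ncol(Xm)
    Q <- (Q + Conj(t(Q))) / 2
  }
  gii <- Re(diag(G))
  Gii <- matrix(gii, m, m)                       # varies along rows: g_ii
  Gjj <- t(Gii)
  Qi <- matrix(Re(diag(Q)), m, m)
  Qj <- t(Qi)
  if (is.null(min_distance)) min_distance <- lead$grid$spacing
  if (is.null(distances)) distances <- cross_dist(lead$grid$positions,
                                                  lead$grid$positions)
  base_valid <- outer(lead$valid & gii > 0, lead$valid & gii > 0, "&")
  diag(base_valid) <- FALSE
  if (method == "dual") {
    absG2e <- Mod(G)^2
    det <- Gii * Gjj - absG2e
    # collinearity guard on the diagonally-normalized pair Gram:
    # cond = (1 + |c|)/(1 - |c|), c = g_ij / sqrt(g_ii g_jj)
    corr2 <- absG2e / (Gii * Gjj)
    corr_cut <- (cond_guard - 1) / (cond_guard + 1)
    valid <- base_valid & (det > 0) & (corr2 <= corr_cut^2) &
      (distances >= min_distance * (1 - 1e-9))
    det2 <- det^2
    cross <- (-G * Gjj * Qi + Gii * Gjj * Q + G * G * Conj(Q) - G * Gii * Qj) / det2
    p1 <- Re(Gjj^2 * Qi - Gjj * Conj(G) * Q - Gjj * G * Conj(Q) + absG2e * Qj) / det2
    p2 <- Re(absG2e * Qi - Gii * Conj(G) * Q - Gii * G * Conj(Q) + Gii^2 * Qj) / det2
    G2i <- matrix(Re(diag(G2)), m, m)
    G2j <- t(G2i)
    inner <- (-G * Gjj * G2i + Gii * Gjj * G2 + G * G * Conj(G2) - G * Gii * G2j) / det2
  } else {
    valid <- base_valid
    den <- Gii * Gjj
    cross <- Q / den
    p1 <- Qi / Gii^2
    p2 <- Qj / Gjj^2
    inner <- G2 / den
  }
  cross[!valid] <- NA_complex_
  p1[!valid] <- NA_real_
  p2[!valid] <- NA_real_
  inner[!valid] <- NA_complex_
  structure(list(cross = cross, p1 = p1, p2 = p2, inner = inner,
                 valid = valid, method = method, grid = lead$grid),
            class = "pair_spectra")
}

#' Naive per-pair reference computation
#'
#' Reference implementation of [all_pairs_csd_power()] that builds the
#' explicit (pair or single) filters for every pair and applies them to the
#' data. Quadratic in dipoles times channels; intended for small problems and
#' as the correctness oracle for the vectorized path.
#'
#' @inheritParams all_pairs_csd_power
#' @export
all_pairs_naive <- function(lead, csd_inv, X, method = c("dual", "single"),
                            distances = NULL, cond_guard = 1e6,
                            min_distance = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(lead, "leadfield"), lead$n_ori == 1L)
  Xm <- coef_of(X)
  n <- ncol(Xm)
  H <- lead$gain
  m <- ncol(H)
  if (is.null(min_distance)) min_distance <- lead$grid$spacing
  if (is.null(distances)) distances <- cross_dist(lead$grid$positions,
                                                  lead$grid$positions)
  cross <- matrix(NA_complex_, m, m)
  p1 <- matrix(NA_real_, m, m)
  p2 <- matrix(NA_real_, m, m)
  inner <- matrix(NA_complex_, m, m)
  valid <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j || !lead$valid[i] || !lead$valid[j]) next
      if (method == "dual") {
        if (distances[i, j] < min_distance * (1 - 1e-9)) next
        W <- tryCatch(pair_filter(H[, i], H[, j], csd_inv, cond_guard),
                      error = function(e) NULL)
        if (is.null(W)) next
        s <- W$weights %*% Xm
        cross[i, j] <- sum(s[1, ] * Conj(s[2, ])) / n
        p1[i, j] <- Re(sum(s[1, ] * Conj(s[1, ]))) / n
        p2[i, j] <- Re(sum(s[2, ] * Conj(s[2, ]))) / n
        inner[i, j] <- sum(W$weights[1, ] * Conj(W$weights[2, ]))
      } else {
        wi <- single_filter(H[, i], csd_inv)$weights
        wj <- single_filter(H[, j], csd_inv)$weights
        si <- drop(wi %*% Xm)
        sj <- drop(wj %*% Xm)
        cross[i, j] <- sum(si * Conj(sj)) / n
        p1[i, j] <- Re(sum(si * Conj(si))) / n
        p2[i, j] <- Re(sum(sj * Conj(sj))) / n
        inner[i, j] <- sum(wi * Conj(wj))
      }
      valid[i, j] <- TRUE
    }
  }
  structure(list(cross = cross, p1 = p1, p2 = p2, inner = inner,
                 valid = valid, method = method, grid = lead$grid),
            class = "pair_spectra")
}
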