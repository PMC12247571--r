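#' Build an MEG-like sensor array on a spherical cap
#'
#' Places `n_channels` point magnetometers approximately uniformly on the
#' upper part of a sphere of the given radius (a helmet-like cap), using a
#' golden-angle spiral. The whole arrangement is rotated about the z-axis by a
#' seed-dependent random angle, so arrays are deterministic per seed and
#' distinct across seeds. Sensor orientations are the outward radial normals.
#'
#' @param n_channels number of sensors (>= 2)
#' @param radius sensor shell radius in meters (must exceed the conductor
#'   radius of the head model the array is used with)
#' @param seed integer seed controlling the azimuthal rotation
#' @param cap_fraction fraction of the full sphere covered by the cap,
#'   measured from the vertex downwards; the default 0.75 reaches well below
#'   the equator, emulating the coverage of a whole-head MEG helmet
#' @return an object of class `sensor_array` with fields `positions`
#'   (n x 3, meters), `orientations` (unit normals), `labels`, `n_channels`,
#'   `radius`
#' @export
build_sensor_array <- function(n_channels, radius, seed = 0L, cap_fraction = 0.75) {
  chk_num(n_channels, "n_channels")
  chk_num(radius, "radius")
  if (n_channels < 2) stop("n_channels must be at least 2", call. = FALSE)
  if (radius <= 0) stop("sensor radius must be positive", call. = FALSE)
  if (cap_fraction <= 0 || cap_fraction > 1) {
    stop("cap_fraction must be in (0, 1]", call. = FALSE)
  }
  k <- seq_len(n_channels) - 0.5
  z <- 1 - 2 * cap_fraction * k / n_channels        # cos(theta), vertex down
  golden <- pi * (1 + sqrt(5))
  rot <- with_seed(derive_seed(seed, 1L), stats::runif(1, 0, 2 * pi))
  az <- golden * k + rot
  rho <- sqrt(pmax(1 - z^2, 0))
  orientations <- cbind(rho * cos(az), rho * sin(az), z)
  structure(list(
    positions = radius * orientations,
    orientations = orientations,
    labels = sprintf("MEG%03d", seq_len(n_channels)),
    n_channels = as.integer(n_channels),
    radius = radius,
    seed = as.integer(seed)
  ), class = "sensor_array")
}

#' Build a regular dipole grid inside a spherical conductor
#'
#' Axis-aligned lattice with the requested spacing, clipped to the strict
#' interior of the conductor sphere (centered at the origin).
#'
#' @param spacing grid spacing in meters, 0 < spacing < conductor_radius
#' @param conductor_radius conductor sphere radius in meters
#' @return an object of class `source_grid` with fields `positions` (m x 3),
#'   `spacing`, `radius`, `inside_mask`, `n_dipoles`
#' @export
build_source_grid <- function(spacing, conductor_radius) {
  chk_num(spacing, "spacing")
  chk_num(conductor_radius, "conductor_radius")
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  if (spacing >= conductor_radius) {
    stop("spacing must be smaller than the conductor radius (empty grid)",
         call. = FALSE)
  }
  nmax <- floor(conductor_radius / spacing)
  ks <- seq(-nmax, nmax)
  # integer-lattice interiority test: deterministic at boundary points
  idx <- as.matrix(expand.grid(x = ks, y = ks, z = ks, KEEP.OUT.ATTRS = FALSE))
  dimnames(idx) <- NULL
  inside <- rowSums(idx^2) * spacing^2 < conductor_radius^2
  pos <- idx[inside, , drop = FALSE] * spacing
  structure(list(
    positions = pos,
    spacing = spacing,
    radius = conductor_radius,
    inside_mask = rep(TRUE, nrow(pos)),
    n_dipoles = nrow(pos)
  ), class = "source_grid")
}

#' Analytic spherical-conductor MEG leadfield
#'
#' Closed-form magnetic field of a current dipole inside a homogeneous
#' conducting sphere, evaluated along each sensor's normal (point
#' magnetometer). Columns are ordered dipole-major: the three
#' free-orientation columns (x, y, z unit moments) of dipole `d` occupy
#' columns `3*(d-1) + 1:3`. Units are tesla per unit dipole moment (A m).
#'
#' A dipole oriented radially, or placed at the sphere center, produces no
#' external magnetic field; such silent configurations come out as
#' (numerically) zero gain. Dipoles at the center or outside the conductor
#' are flagged invalid (`valid` attribute) and their columns zeroed.
#'
#' @param grid a `source_grid`
#' @param sensors a `sensor_array`; all sensors must lie outside the conductor
#' @param center conductor center, default the origin
#' @return an object of class `leadfield`: `gain` (channels x 3*n_dipoles),
#'   `n_ori = 3`, `valid` per dipole, plus references to grid and sensors
#' @export
sphere_leadfield <- function(grid, sensors, center = c(0, 0, 0)) {
  stopifnot(inherits(grid, "source_grid"), inherits(sensors, "sensor_array"))
  r0 <- sweep(grid$positions, 2, center)          # dipole positions (m x 3)
  m <- nrow(r0)
  nch <- sensors$n_channels
  sens <- sweep(sensors$positions, 2, center)
  if (any(row_norms(sens) <= grid$radius)) {
    stop("all sensors must lie outside the conductor sphere", call. = FALSE)
  }
  r0n <- row_norms(r0)
  valid <- r0n > 1e-9 & r0n < grid$radius
  gain <- matrix(0, nch, 3L * m)
  mu0_4pi <- 1e-7
  # unit moments along the coordinate axes; Q x r0 for Q = e_k
  qxr <- list(
    cbind(0, -r0[, 3], r0[, 2]),   # e_x x r0 = (0, -z, y)... see below
    cbind(r0[, 3], 0, -r0[, 1]),
    cbind(-r0[, 2], r0[, 1], 0)
  )
  # note: e_x x r0 = (0*z - 0*y, 0*x - 1*z, 1*y - 0*x) = (0, -z, y)
  for (c in seq_len(nch)) {
    r <- sens[c, ]
    nrm <- sensors$orientations[c, ]
    a <- sweep(-r0, 2, r, "+")                    # a = r - r0 (m x 3)
    an <- row_norms(a)
    R <- sqrt(sum(r^2))
    adotr <- drop(a %*% r)
    r0dotr <- drop(r0 %*% r)
    F <- an * (R * an + R^2 - r0dotr)
    c1 <- an^2 / R + adotr / an + 2 * an + 2 * R
    c2 <- an + 2 * R + adotr / an
    gradF <- outer(c1, r) - c2 * r0               # m x 3
    for (k in 1:3) {
      qr <- qxr[[k]]
      qrdotr <- drop(qr %*% r)
      B <- (F * qr - qrdotr * gradF) / F^2 * mu0_4pi
      gain[c, 3L * (seq_len(m) - 1L) + k] <- B %*% nrm
    }
  }
  bad <- !valid
  if (any(bad)) {
    idx <- rep(3L * (which(bad) - 1L), each = 3L) + 1:3
    gain[, idx] <- 0
  }
  structure(list(
    gain = gain,
    n_ori = 3L,
    valid = valid,
    grid = grid,
    sensors = sensors,
    units = "T per A*m"
  ), class = "leadfield")
}

# per-dipole gain norm, free (3-column blocks) or oriented leadfields
leadfield_norms <- function(lead) {
  g2 <- colSums(lead$gain^2)
  if (lead$n_ori == 3L) {
    m <- length(g2) / 3L
    sqrt(g2[3 * seq_len(m) - 2] + g2[3 * seq_len(m) - 1] + g2[3 * seq_len(m)])
  } else {
    sqrt(g2)
  }
}

#' Screen candidate source locations by array sensitivity
#'
#' Ranks dipoles by gain-vector norm and keeps the top fraction, mimicking the
#' exclusion of locations to which the sensor array is relatively insensitive
#' (deep or unfavorably oriented dipoles). Ties at the cut are resolved in
#' favor of the lower dipole index.
#'
#' @param lead a `leadfield` (free or oriented)
#' @param keep_fraction fraction of dipoles to retain, in (0, 1]
#' @return sorted integer vector of retained dipole indices
#' @export
screen_candidate_sources <- function(lead, keep_fraction = 0.4) {
  chk_num(keep_fraction, "keep_fraction")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  }
  norms <- leadfield_norms(lead)
  if (all(norms == 0)) stop("leadfield is identically zero", call. = FALSE)
  n <- length(norms)
  n_keep <- max(1L, as.integer(round_half_up(keep_fraction * n)))
  ord <- order(-norms, seq_len(n))               # stable: lowest index first
  sort(ord[seq_len(min(n_keep, n))])
}
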