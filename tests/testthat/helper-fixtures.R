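# Shared small-scale fixtures, built once per test run.

# toy forward workspace: ~57-dipole grid, 40 sensors
tiny_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- setup_forward(n_channels = 40L, sensor_radius = 0.12,
                              conductor_radius = 0.08, spacing = 0.035,
                              keep_fraction = 0.5, seed = 1L)
    }
    cache
  }
})

# mid-size workspace for pipeline-level checks: ~130 dipoles, 90 sensors
small_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- setup_forward(n_channels = 90L, sensor_radius = 0.12,
                              conductor_radius = 0.08, spacing = 0.026,
                              keep_fraction = 0.5, seed = 2L)
    }
    cache
  }
})

# restrict an oriented leadfield (and its grid) to a dipole subset
subset_leadfield <- function(lead, keep) {
  stopifnot(lead$n_ori == 1L)
  out <- lead
  out$gain <- lead$gain[, keep, drop = FALSE]
  out$valid <- lead$valid[keep]
  out$orientations <- lead$orientations[keep, , drop = FALSE]
  g <- lead$grid
  g$positions <- g$positions[keep, , drop = FALSE]
  g$inside_mask <- g$inside_mask[keep]
  g$n_dipoles <- length(keep)
  out$grid <- g
  out
}

# oriented leadfield + csd inverse for a simulated dataset on a setup
oriented_pipeline <- function(setup, sim) {
  ci <- invert_csd(sensor_csd(sim$X))
  list(ci = ci, lead = orient_leadfield(setup$lead, ci))
}

# brute-force lattice count of grid points strictly inside a sphere
lattice_count_oracle <- function(spacing, radius) {
  nmax <- floor(radius / spacing)
  count <- 0L
  for (ix in -nmax:nmax) for (iy in -nmax:nmax) for (iz in -nmax:nmax) {
    if ((ix^2 + iy^2 + iz^2) * spacing^2 < radius^2) count <- count + 1L
  }
  count
}

row_norms_test <- function(m) sqrt(rowSums(m^2))

# independent clustering oracle: full pairwise adjacency + igraph components
cluster_oracle <- function(edgeset, grid, neighborhood = 26) {
  edges <- edgeset$edges
  E <- nrow(edges)
  if (E == 0) return(list())
  mult <- switch(as.character(neighborhood), "26" = sqrt(3), "18" = sqrt(2),
                 "6" = 1)
  r <- grid$spacing * mult * (1 + 1e-9) + 1e-12
  pos <- grid$positions
  adj <- matrix(FALSE, E, E)
  for (a in seq_len(E)) for (b in seq_len(E)) {
    dik <- sqrt(sum((pos[edges$i[a], ] - pos[edges$i[b], ])^2))
    djl <- sqrt(sum((pos[edges$j[a], ] - pos[edges$j[b], ])^2))
    dil <- sqrt(sum((pos[edges$i[a], ] - pos[edges$j[b], ])^2))
    djk <- sqrt(sum((pos[edges$j[a], ] - pos[edges$i[b], ])^2))
    adj[a, b] <- (dik <= r && djl <= r) || (dil <= r && djk <= r)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(seq_len(E), comp))
}

# canonical form of a clustering (sorted members, sorted lexicographically)
canonical_clusters <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, function(x) x[1], integer(1)))]
}
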