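#' Relative thresholding of a pairwise volume
#'
#' Keeps the largest values of a corrected coherence (or z) volume. The edge
#' count is `round(pct/100 * N^2)` with `N` the number of grid dipoles, i.e.,
#' the percentage refers to the full N x N matrix, while each unordered pair
#' is emitted once (the volume is symmetric, so both orderings of a pair
#' cross the threshold together). The diagonal and invalid entries are masked
#' before selection; ties at the cut are broken by the lower flat
#' (column-major) index.
#'
#' @param volume a `coherence_volume`, `subsample_aggregate` z map, or plain
#'   numeric matrix
#' @param pct threshold percentage in (0, 100]
#' @param valid optional validity mask overriding the volume's own
#' @return object of class `edge_set`: data frame `edges` (i, j, value; i < j),
#'   `pct`, `n_grid`, `n_edges`
#' @export
threshold_edges <- function(volume, pct, valid = NULL) {
  chk_num(pct, "pct")
  if (pct <= 0 || pct > 100) stop("pct must be in (0, 100]", call. = FALSE)
  if (inherits(volume, "coherence_volume")) {
    vals <- volume$values
    if (is.null(valid)) valid <- volume$valid
  } else if (inherits(volume, "subsample_aggregate")) {
    vals <- volume$z
    if (is.null(valid)) valid <- volume$valid
  } else {
    vals <- volume
  }
  stopifnot(is.matrix(vals), nrow(vals) == ncol(vals))
  m <- nrow(vals)
  if (m < 2) stop("volume has no off-diagonal entries", call. = FALSE)
  n_edges <- as.integer(round_half_up(pct / 100 * as.double(m)^2))
  ut <- which(upper.tri(vals))
  v <- vals[ut]
  if (!is.null(valid)) v[!valid[ut]] <- -Inf
  v[!is.finite(v)] <- -Inf
  if (all(v == -Inf)) stop("volume has no valid entries to threshold", call. = FALSE)
  n_take <- min(n_edges, sum(v > -Inf))
  edges <- if (n_take >= 1) {
    ord <- order(-v, ut)[seq_len(n_take)]
    flat <- ut[ord]
    i <- ((flat - 1L) %% m) + 1L
    j <- ((flat - 1L) %/% m) + 1L
    data.frame(i = i, j = j, value = vals[flat])
  } else {
    data.frame(i = integer(), j = integer(), value = numeric())
  }
  structure(list(edges = edges, pct = pct, n_grid = m,
                 n_edges = n_edges),
            class = "edge_set")
}

#' Cluster suprathreshold edges in 6-dimensional space
#'
#' Two edges (i, j) and (k, l) are adjacent iff both endpoint distances are
#' within the 3-D neighborhood radius simultaneously, for either endpoint
#' pairing: `(d(i,k) <= r & d(j,l) <= r) | (d(i,l) <= r & d(j,k) <= r)`,
#' with `r = spacing * sqrt(3)` for the default 26-neighborhood per side
#' (18- and 6-neighborhoods select `sqrt(2)` and `1` times the spacing).
#' Connected components of this adjacency are the clusters. Computed
#' blockwise to bound memory; equivalent to brute-force pairwise union-find.
#'
#' @param edgeset an `edge_set`
#' @param grid the `source_grid` the indices refer to
#' @param neighborhood 26 (default), 18, or 6
#' @return list of integer vectors, each giving the row indices (into
#'   `edgeset$edges`) of one cluster
#' @export
cluster_edges_6d <- function(edgeset, grid, neighborhood = 26) {
  stopifnot(inherits(edgeset, "edge_set"), inherits(grid, "source_grid"))
  edges <- edgeset$edges
  E <- nrow(edges)
  if (E == 0) return(list())
  mult <- switch(as.character(neighborhood),
                 "26" = sqrt(3), "18" = sqrt(2), "6" = 1,
                 stop("neighborhood must be one of 6, 18, 26", call. = FALSE))
  r <- grid$spacing * mult * (1 + 1e-9) + 1e-12
  pos_i <- grid$positions[edges$i, , drop = FALSE]
  pos_j <- grid$positions[edges$j, , drop = FALSE]
  parent <- seq_len(E)
  # union-find with path halving, closing over `parent`
  uf_find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  block <- 2048L
  starts <- seq(1L, E, by = block)
  for (ba in starts) {
    ea <- seq(ba, min(ba + block - 1L, E))
    for (bb in starts[starts >= ba]) {
      eb <- seq(bb, min(bb + block - 1L, E))
      dik <- cross_dist(pos_i[ea, , drop = FALSE], pos_i[eb, , drop = FALSE])
      djl <- cross_dist(pos_j[ea, , drop = FALSE], pos_j[eb, , drop = FALSE])
      dil <- cross_dist(pos_i[ea, , drop = FALSE], pos_j[eb, , drop = FALSE])
      djk <- cross_dist(pos_j[ea, , drop = FALSE], pos_i[eb, , drop = FALSE])
      adj <- (dik <= r & djl <= r) | (dil <= r & djk <= r)
      hits <- which(adj, arr.ind = TRUE)
      if (nrow(hits) > 0) {
        for (h in seq_len(nrow(hits))) {
          x <- ea[hits[h, 1]]
          y <- eb[hits[h, 2]]
          if (x >= y) next
          rx <- uf_find(x)
          ry <- uf_find(y)
          if (rx != ry) parent[min(rx, ry)] <- parent[max(rx, ry)] <- min(rx, ry)
        }
      }
    }
  }
  roots <- vapply(seq_len(E), function(x) uf_find(x), integer(1))
  unname(split(seq_len(E), roots))
}

#' Classify clusters into valid connections and discarded auto-connections
#'
#' Edges within each cluster are canonically oriented by a consistency pass
#' (the endpoint nearer the cluster's first-assembly centroid goes to
#' assembly A), then assembly A is the set of first endpoints and assembly B
#' the set of second endpoints. Clusters whose assemblies share a dipole
#' (auto-connections) are discarded as leakage-driven.
#'
#' @param clusters output of [cluster_edges_6d()]
#' @param edgeset the thresholded `edge_set`
#' @param grid the `source_grid`
#' @return list with `connections` (each: `assembly_a`, `assembly_b` dipole
#'   index sets, `edge_rows`, `max_value`) and `n_discarded`
#' @export
filter_clusters <- function(clusters, edgeset, grid) {
  stopifnot(inherits(edgeset, "edge_set"), inherits(grid, "source_grid"))
  edges <- edgeset$edges
  pos <- grid$positions
  connections <- list()
  n_discarded <- 0L
  for (cl in clusters) {
    ei <- edges$i[cl]
    ej <- edges$j[cl]
    # anchor the orientation pass on the cluster's peak edge: its endpoints
    # seed the two assembly centroids
    peak <- which.max(edges$value[cl])
    ai <- ei; bi <- ej
    cA <- pos[ei[peak], ]
    cB <- pos[ej[peak], ]
    for (pass in 1:3) {
      dA_i <- sqrt(colSums((t(pos[ei, , drop = FALSE]) - cA)^2))
      dB_i <- sqrt(colSums((t(pos[ei, , drop = FALSE]) - cB)^2))
      dA_j <- sqrt(colSums((t(pos[ej, , drop = FALSE]) - cA)^2))
      dB_j <- sqrt(colSums((t(pos[ej, , drop = FALSE]) - cB)^2))
      swap <- (dA_i + dB_j) > (dB_i + dA_j)
      nai <- ifelse(swap, ej, ei)
      nbi <- ifelse(swap, ei, ej)
      converged <- all(nai == ai)
      ai <- nai; bi <- nbi
      cA <- colMeans(pos[ai, , drop = FALSE])
      cB <- colMeans(pos[bi, , drop = FALSE])
      if (converged) break
    }
    A <- unique(ai); B <- unique(bi)
    if (length(intersect(A, B)) > 0) {
      n_discarded <- n_discarded + 1L
    } else {
      connections[[length(connections) + 1L]] <-
        list(assembly_a = sort(A), assembly_b = sort(B), edge_rows = cl,
             max_value = max(edges$value[cl]))
    }
  }
  list(connections = connections, n_discarded = n_discarded)
}

#' Score detected connections against the true dipole pair
#'
#' A hit requires some valid connection whose assemblies jointly approach the
#' true pair: the summed distance (true dipole 1 to its nearest assembly
#' dipole, plus true dipole 2 to the other assembly's nearest dipole) must
#' not exceed the tolerance, evaluated over both assembly pairings. All
#' non-matching valid connections count as false positives.
#'
#' @param connections `connections` element from [filter_clusters()]
#' @param true_positions 2 x 3 matrix of true dipole positions (meters)
#' @param grid the `source_grid`
#' @param tolerance summed-distance tolerance in meters (default 0.02)
#' @return list with `hit`, `n_false_positives`, `n_connections`
#' @export
score_detection <- function(connections, true_positions, grid,
                            tolerance = 0.02) {
  stopifnot(is.matrix(true_positions), nrow(true_positions) == 2)
  pos <- grid$positions
  t1 <- true_positions[1, ]; t2 <- true_positions[2, ]
  matched <- vapply(connections, function(cn) {
    pa <- pos[cn$assembly_a, , drop = FALSE]
    pb <- pos[cn$assembly_b, , drop = FALSE]
    d1a <- min(sqrt(colSums((t(pa) - t1)^2)))
    d1b <- min(sqrt(colSums((t(pb) - t1)^2)))
    d2a <- min(sqrt(colSums((t(pa) - t2)^2)))
    d2b <- min(sqrt(colSums((t(pb) - t2)^2)))
    min(d1a + d2b, d1b + d2a) <= tolerance
  }, logical(1))
  list(hit = any(matched),
       n_false_positives = sum(!matched),
       n_connections = length(connections))
}

#' Free-response ROC curve
#'
#' Per threshold: hit rate is the fraction of configurations with a hit, and
#' the false-positive count is the mean over configurations. Because the
#' relative-threshold edge sets are nested, the mean false-positive count is
#' non-decreasing in the threshold percentage.
#'
#' @param reports data frame with columns `config`, `pct`, `hit`, `n_fp`
#'   (one row per configuration x threshold)
#' @return data frame with `pct`, `hit_rate`, `mean_fp`, ordered by
#'   decreasing `pct`
#' @export
froc <- function(reports) {
  stopifnot(all(c("config", "pct", "hit", "n_fp") %in% names(reports)),
            nrow(reports) >= 1)
  pcts <- sort(unique(reports$pct), decreasing = TRUE)
  out <- do.call(rbind, lapply(pcts, function(p) {
    sub <- reports[reports$pct == p, , drop = FALSE]
    data.frame(pct = p,
               hit_rate = mean(sub$hit),
               mean_fp = mean(sub$n_fp))
  }))
  rownames(out) <- NULL
  out
}
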