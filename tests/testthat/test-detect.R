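test_that("relative thresholding keeps the right count with a stable tie rule", {
  # 3x3 toy: keep exactly the largest off-diagonal entry
  v <- matrix(c(0, 5, 1,
                5, 0, 2,
                1, 2, 0), 3, 3, byrow = TRUE)
  es <- threshold_edges(v, 100 / 9)   # round(1/9 * 9) = 1 edge
  expect_equal(nrow(es$edges), 1L)
  expect_equal(c(es$edges$i, es$edges$j), c(1L, 2L))

  # tie at the cut: lower flat index wins
  vt <- matrix(0, 4, 4); vt[1, 2] <- vt[2, 1] <- 3
  vt[1, 3] <- vt[3, 1] <- 3; vt[1, 4] <- vt[4, 1] <- 1
  es <- threshold_edges(vt, 100 / 16)   # keep 1
  expect_equal(c(es$edges$i, es$edges$j), c(1L, 2L))

  # edge sets are nested along a decreasing threshold ladder
  set.seed(5)
  m <- 80
  vv <- matrix(rnorm(m * m), m, m); vv <- vv + t(vv)
  key <- function(es) paste(es$edges$i, es$edges$j)
  ladder <- c(5, 1, 0.5, 0.1, 0.05)
  sets <- lapply(ladder, function(p) key(threshold_edges(vv, p)))
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k + 1]] %in% sets[[k]]))
  }

  expect_error(threshold_edges(matrix(0, 1, 1), 1), "off-diagonal")
})

test_that("6-D clustering matches the brute-force adjacency oracle", {
  skip_if_not_installed("igraph")
  grid <- build_source_grid(0.02, 0.08)
  m <- grid$n_dipoles
  set.seed(8)
  for (rep in 1:5) {
    E <- sample(20:120, 1)
    i <- sample(m, E, replace = TRUE)
    j <- sample(m, E, replace = TRUE)
    keep <- i != j
    edges <- data.frame(i = pmin(i, j)[keep], j = pmax(i, j)[keep],
                        value = runif(sum(keep)))
    edges <- edges[!duplicated(edges[, 1:2]), ]
    es <- structure(list(edges = edges, pct = 1, n_grid = m,
                         n_edges = nrow(edges)), class = "edge_set")
    got <- canonical_clusters(cluster_edges_6d(es, grid))
    want <- canonical_clusters(cluster_oracle(es, grid))
    expect_identical(got, want)
  }
})

test_that("clustering handles the documented toy geometries", {
  grid <- build_source_grid(0.02, 0.08)
  pos <- grid$positions
  # find an axis-aligned neighbor pair and a far-away pair
  near_of <- function(d, step) {
    target <- pos[d, ] + c(step, 0, 0)
    which(colSums((t(pos) - target)^2) < 1e-18)[1]
  }
  a <- which(pos[, 1] == 0 & pos[, 2] == 0 & pos[, 3] == 0.04)[1]
  b <- near_of(a, 0.02)
  far1 <- which(pos[, 1] == -0.04 & pos[, 2] == 0 & pos[, 3] == -0.04)[1]
  far2 <- near_of(far1, 0.02)

  mk <- function(df) structure(list(edges = df, pct = 1, n_grid = nrow(pos),
                                    n_edges = nrow(df)), class = "edge_set")
  # single edge: one cluster of size 1
  cl <- cluster_edges_6d(mk(data.frame(i = a, j = far1, value = 1)), grid)
  expect_length(cl, 1)
  expect_length(cl[[1]], 1)

  # two edges sharing endpoint a, other endpoints one grid step apart
  cl <- cluster_edges_6d(mk(data.frame(i = c(a, a), j = c(far1, far2),
                                       value = c(1, 2))), grid)
  expect_length(cl, 1)

  # two edges whose nearest endpoints are 5 grid steps apart
  c5 <- which(pos[, 1] == 0 & pos[, 2] == 0.02 * 5 & pos[, 3] == 0.04)[1]
  cl <- cluster_edges_6d(mk(data.frame(i = c(a, c5), j = c(far1, far1 + 0),
                                       value = c(1, 2))), grid)
  expect_length(cl, 2)
})

test_that("auto-connected clusters are discarded, disjoint assemblies kept", {
  grid <- build_source_grid(0.02, 0.08)
  pos <- grid$positions
  at <- function(x, y, z) which(pos[, 1] == x & pos[, 2] == y & pos[, 3] == z)[1]
  a <- at(0, 0, 0.04); a2 <- at(0.02, 0, 0.04); a3 <- at(0.04, 0, 0.04)
  b <- at(0, 0, -0.04); b2 <- at(0.02, 0, -0.04)
  c1 <- at(-0.04, 0, 0); c2 <- at(-0.04, 0.02, 0)

  # cluster 1: a chain (a, a2), (a2, a3) whose assemblies share a2 ->
  #            auto-connection, discarded
  # cluster 2: (a, b), (a2, b2) with disjoint assemblies {a, a2} / {b, b2}
  # cluster 3: single short edge far away, disjoint singleton assemblies
  edges <- data.frame(i = c(a, a2, a, a2, c1),
                      j = c(a2, a3, b, b2, c2),
                      value = 1:5)
  es <- structure(list(edges = edges, pct = 1, n_grid = nrow(pos),
                       n_edges = nrow(edges)), class = "edge_set")
  cl <- cluster_edges_6d(es, grid)
  expect_length(cl, 3)
  fc <- filter_clusters(cl, es, grid)
  expect_equal(fc$n_discarded, 1L)
  expect_length(fc$connections, 2L)
  conns <- fc$connections[order(vapply(fc$connections,
                                       function(x) x$assembly_a[1], integer(1)))]
  expect_equal(conns[[1]]$assembly_a, sort(c(c1)))
  expect_equal(conns[[1]]$assembly_b, sort(c(c2)))
  expect_setequal(unlist(lapply(conns[2], `[[`, "assembly_a")), c(a, a2))
  expect_setequal(unlist(lapply(conns[2], `[[`, "assembly_b")), c(b, b2))
})

test_that("hits and false positives are scored by summed assembly distance", {
  grid <- build_source_grid(0.02, 0.08)
  pos <- grid$positions
  true_pos <- pos[c(10, 200), ]
  conn <- function(A, B) list(assembly_a = A, assembly_b = B, edge_rows = 1L,
                              max_value = 1)
  exact <- conn(10L, 200L)
  far <- conn(30L, 150L)
  # a connection exactly at the pair
  sc <- score_detection(list(exact), true_pos, grid)
  expect_true(sc$hit); expect_equal(sc$n_false_positives, 0L)
  # no connections
  sc0 <- score_detection(list(), true_pos, grid)
  expect_false(sc0$hit); expect_equal(sc0$n_false_positives, 0L)
  # swapped assemblies still match (both pairings evaluated)
  sc_sw <- score_detection(list(conn(200L, 10L)), true_pos, grid)
  expect_true(sc_sw$hit)
  # one matching plus two distant connections
  d_far <- min(sqrt(sum((pos[30, ] - true_pos[1, ])^2)) +
                 sqrt(sum((pos[150, ] - true_pos[2, ])^2)),
               sqrt(sum((pos[30, ] - true_pos[2, ])^2)) +
                 sqrt(sum((pos[150, ] - true_pos[1, ])^2)))
  expect_gt(d_far, 0.02)   # fixture sanity
  sc3 <- score_detection(list(exact, far, conn(40L, 160L)), true_pos, grid)
  expect_true(sc3$hit); expect_equal(sc3$n_false_positives, 2L)
})

test_that("FROC aggregation reduces reports to hit rate vs mean false positives", {
  # all configurations hit with 0 FP: flat curve at (0, 1)
  rep0 <- expand.grid(config = 1:4, pct = c(1, 0.1))
  rep0$hit <- TRUE; rep0$n_fp <- 0
  fr <- froc(rep0)
  expect_true(all(fr$hit_rate == 1) && all(fr$mean_fp == 0))

  # hand-built 2 configurations x 2 thresholds
  rep1 <- data.frame(config = c(1, 1, 2, 2), pct = c(1, 0.1, 1, 0.1),
                     hit = c(TRUE, FALSE, TRUE, TRUE), n_fp = c(10, 2, 20, 4))
  fr1 <- froc(rep1)
  expect_equal(fr1$pct, c(1, 0.1))
  expect_equal(fr1$hit_rate, c(1, 0.5))
  expect_equal(fr1$mean_fp, c(15, 3))
})
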