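test_that("CSD inversion is exact when full rank and Penrose-valid otherwise", {
  expect_equal(invert_csd(diag(3) + 0i)$inv, diag(3) + 0i, tolerance = 1e-12)
  expect_equal(invert_csd(diag(c(2, 4)) + 0i)$inv, diag(c(0.5, 0.25)) + 0i,
               tolerance = 1e-12)

  # rank-1 Hermitian matrix: pseudo-inverse satisfies the four Penrose
  # conditions
  v <- complex(real = rnorm(4), imaginary = rnorm(4))
  C <- outer(v, Conj(v))
  pi_ <- invert_csd(C)
  A <- C; Ap <- pi_$inv
  expect_equal(pi_$rank, 1L)
  expect_lt(max(Mod(A %*% Ap %*% A - A)), 1e-8 * max(Mod(A)))
  expect_lt(max(Mod(Ap %*% A %*% Ap - Ap)), 1e-8 * max(Mod(Ap)))
  expect_lt(max(Mod(A %*% Ap - Conj(t(A %*% Ap)))), 1e-8 * max(Mod(A %*% Ap)))
  expect_lt(max(Mod(Ap %*% A - Conj(t(Ap %*% A)))), 1e-8 * max(Mod(Ap %*% A)))

  bad <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  expect_error(invert_csd(bad), "Hermitian")
})

test_that("fixed orientation maximizes output power in the gain column space", {
  # only one nonzero column: orientation along that axis
  H <- cbind(rnorm(8), 0, 0)
  fo <- fixed_orientation(H, diag(8) + 0i)
  expect_equal(abs(fo$orientation), c(1, 0, 0), tolerance = 1e-12)

  # C = I, orthogonal columns with norms 1, 2, 3: 3x3 Gram is
  # diag(1, 4, 9); smallest eigenvalue belongs to the norm-1 column
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))[, 1:3]
  H <- Q %*% diag(c(1, 2, 3))
  fo <- fixed_orientation(H, diag(8) + 0i)
  expect_equal(abs(fo$orientation), c(1, 0, 0), tolerance = 1e-8)
  expect_equal(sqrt(sum(fo$orientation^2)), 1, tolerance = 1e-12)

  # batch orientation agrees with the per-dipole routine
  setup <- tiny_setup()
  sim <- simulate_dataset(setup$lead, setup$candidates, 0.5, pi / 4, 0.7, 0.7,
                          n_sources = 6, n_obs = 200, seed = 11)
  ci <- invert_csd(sensor_csd(sim$X))
  ol <- orient_leadfield(setup$lead, ci)
  for (d in which(ol$valid)[c(2, 9, 17)]) {
    fo <- fixed_orientation(setup$lead$gain[, 3 * (d - 1) + 1:3], ci)
    expect_equal(ol$orientations[d, ], fo$orientation, tolerance = 1e-8)
  }
})

test_that("single filters satisfy unit gain and LCMV closed forms", {
  h <- rnorm(6)
  # C = I: w = h' / (h'h)
  w <- single_filter(h, diag(6) + 0i)$weights
  expect_equal(w, h / sum(h^2) + 0i, tolerance = 1e-12)

  # random full-rank Hermitian C: unit gain and homogeneity
  B <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6, 6)
  C <- B %*% Conj(t(B)) + 6 * diag(6)
  ci <- invert_csd(C)
  w <- single_filter(h, ci)$weights
  expect_equal(sum(w * h), 1 + 0i, tolerance = 1e-8)
  w2 <- single_filter(3 * h, ci)$weights
  expect_equal(w2, w / 3, tolerance = 1e-10)
})

test_that("pair filters satisfy the identity-gain constraint", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 10
    h1 <- rnorm(n); h2 <- rnorm(n)
    B <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
    C <- B %*% Conj(t(B)) + n * diag(n)
    ci <- invert_csd(C)
    W <- pair_filter(h1, h2, ci)$weights
    expect_lt(max(Mod(W %*% cbind(h1, h2) - diag(2))), 1e-8)
    # swapping the dipoles swaps the rows
    W2 <- pair_filter(h2, h1, ci)$weights
    expect_equal(W2, W[2:1, ], tolerance = 1e-10)
  }

  # orthogonal gains with C = I: rows equal the single-dipole filters
  h1 <- c(1, 0, 0, 0, 2); h2 <- c(0, 3, 0, 0, 0)
  W <- pair_filter(h1, h2, diag(5) + 0i)$weights
  expect_equal(W[1, ], single_filter(h1, diag(5) + 0i)$weights,
               tolerance = 1e-12)
  expect_equal(W[2, ], single_filter(h2, diag(5) + 0i)$weights,
               tolerance = 1e-12)

  # near-collinear pair rejected
  expect_error(pair_filter(h1, h1 * 2 + 1e-12, diag(5) + 0i), "collinear")
})

test_that("vectorized all-pairs computation equals the naive per-pair loop", {
  setup <- tiny_setup()
  sim <- simulate_dataset(setup$lead, setup$candidates, 0.6, pi / 3, 0.7, 0.7,
                          n_sources = 6, n_obs = 120, seed = 5)
  pp <- oriented_pipeline(setup, sim)
  keep <- which(pp$lead$valid)[seq(1, 50, by = 5)]   # 10-dipole toy
  lead10 <- subset_leadfield(pp$lead, keep)

  for (method in c("dual", "single")) {
    pv <- all_pairs_csd_power(lead10, pp$ci, X = sim$X, method = method)
    pn <- all_pairs_naive(lead10, pp$ci, sim$X, method = method)
    expect_identical(pv$valid, pn$valid)
    ok <- pv$valid
    expect_true(any(ok))
    for (f in c("cross", "p1", "p2", "inner")) {
      expect_lt(max(Mod(pv[[f]][ok] - pn[[f]][ok]) /
                      pmax(Mod(pn[[f]][ok]), 1e-300)), 1e-10)
    }
    # diagonal pairs excluded, powers real and non-negative
    expect_false(any(diag(pv$valid)))
    expect_true(all(pv$p1[ok] >= 0) && all(pv$p2[ok] >= 0))
  }

  # the data-free path (C^-1 C C^-1 = C^-1 identity) matches as well
  pv0 <- all_pairs_csd_power(lead10, pp$ci, X = NULL, method = "dual")
  pn <- all_pairs_naive(lead10, pp$ci, sim$X, method = "dual")
  ok <- pv0$valid
  expect_lt(max(Mod(pv0$cross[ok] - pn$cross[ok]) / pmax(Mod(pn$cross[ok]), 1e-300)),
            1e-8)

  # the compiled dual-pair kernel agrees with the reference quantities
  H <- lead10$gain
  A <- pp$ci$inv %*% H
  G <- crossprod(Conj(H), A)
  G2 <- crossprod(Conj(A), A)
  D <- beamconn:::cross_dist(lead10$grid$positions, lead10$grid$positions)
  km <- beamconn:::.dual_pair_maps(G, G2, lead10$valid, D,
                                   lead10$grid$spacing, 1e6)
  expect_identical(km$valid, pv0$valid)
  expect_equal(km$abs_cross[ok], Mod(pv0$cross[ok]), tolerance = 1e-10)
  expect_equal(km$abs_inner[ok], Mod(pv0$inner[ok]), tolerance = 1e-10)
  expect_equal(km$coh[ok], Mod(pv0$cross[ok]) / sqrt(pv0$p1[ok] * pv0$p2[ok]),
               tolerance = 1e-10)
})

test_that("pair filters cancel mutual leakage exactly on a two-source mixture", {
  setup <- tiny_setup()
  ci0 <- invert_csd(sensor_csd(generate_noise(setup$sensors$n_channels, 200,
                                              seed = 2)))
  ol <- orient_leadfield(setup$lead, ci0)
  ok <- which(ol$valid)
  i <- ok[4]; j <- ok[30]
  h1 <- ol$gain[, i]; h2 <- ol$gain[, j]
  S <- draw_complex_gaussian(source_csd_matrix(0.4, pi / 5, 0.6, 2), 150,
                             seed = 3)$coefficients
  X <- cbind(h1, h2) %*% S
  ci <- invert_csd(sensor_csd(X))
  W <- pair_filter(h1, h2, ci)$weights
  Shat <- W %*% X
  expect_lt(max(Mod(Shat - S)) / max(Mod(S)), 1e-8)
})
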