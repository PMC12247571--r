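test_that("coherence magnitude behaves at its limits and recovers rho", {
  expect_equal(coherence(3 + 0i, 3, 3), 1)
  expect_equal(coherence(0 + 0i, 2, 5), 0)
  expect_true(is.na(coherence(1 + 0i, 0, 1)))

  # Monte-Carlo recovery from the generator, no mixing: rho = 0.5 at
  # phi = (8/17) pi
  S <- draw_complex_gaussian(source_csd_matrix(0.5, (8 / 17) * pi, 0.7, 2),
                             1e4, seed = 77)$coefficients
  cs <- sum(S[1, ] * Conj(S[2, ]))
  coh <- coherence(cs, sum(Mod(S[1, ])^2), sum(Mod(S[2, ])^2))
  expect_lt(abs(coh - 0.5), 0.02)
})

test_that("imaginary coherency vanishes at zero phase and peaks at 90 degrees", {
  # population coherency from the exact CSD
  M <- source_csd_matrix(0.5, 0, 0.7, 2)
  expect_equal(Im(M[1, 2]) / sqrt(Re(M[1, 1]) * Re(M[2, 2])), 0)

  S <- draw_complex_gaussian(source_csd_matrix(0.5, pi / 2, 0.7, 2), 1e4,
                             seed = 78)$coefficients
  cs <- sum(S[1, ] * Conj(S[2, ]))
  p1 <- sum(Mod(S[1, ])^2); p2 <- sum(Mod(S[2, ])^2)
  expect_lt(abs(abs(Im(cs / sqrt(p1 * p2))) - 0.5), 0.03)

  # |Im(coherency)| never exceeds the coherence magnitude
  for (phi in c(0.3, 1.1, 2.9)) {
    Sx <- draw_complex_gaussian(source_csd_matrix(0.6, phi, 0.6, 2), 500,
                                seed = round(phi * 100))$coefficients
    cs <- sum(Sx[1, ] * Conj(Sx[2, ]))
    pp <- sqrt(sum(Mod(Sx[1, ])^2) * sum(Mod(Sx[2, ])^2))
    expect_lte(abs(Im(cs / pp)), Mod(cs) / pp + 1e-12)
  }
})

test_that("the null-scale regression is exact on proportional input and unbiased", {
  x <- runif(50, 0.1, 2)
  expect_equal(fit_null_scale(3.7 * x, x), 3.7, tolerance = 1e-10)

  # unbiasedness under zero-mean symmetric perturbation
  set.seed(99)
  reps <- replicate(200, {
    xi <- runif(120, 0.1, 1)
    yi <- 2.5 * xi + rnorm(120, 0, 0.1)
    fit_null_scale(yi, xi)
  })
  expect_lt(abs(mean(reps) - 2.5), 3 * sd(reps) / sqrt(200) + 1e-3)

  expect_error(fit_null_scale(1:5, 1:5), "at least")
})

test_that("null coherence matches observed coherence on source-free white noise", {
  setup <- small_setup()
  keep <- which(setup$lead$valid)
  X <- generate_noise(setup$sensors$n_channels, 350, seed = 31)
  ci <- invert_csd(sensor_csd(X))
  ol <- orient_leadfield(setup$lead, ci)
  keep <- which(ol$valid)[seq_len(min(50, sum(ol$valid)))]
  lead50 <- subset_leadfield(ol, keep)
  pr <- all_pairs_csd_power(lead50, ci, X = NULL, method = "dual")
  coh <- coherence_volume(pr)
  nul <- null_coherence_volume(pr)
  ok <- coh$valid & nul$valid
  expect_gt(sum(ok), 100)
  expect_lt(median(abs(coh$values[ok] - nul$values[ok])), 0.05)

  # scaling all gain columns leaves the null coherence invariant
  lead_s <- lead50
  lead_s$gain <- lead50$gain * 3.7
  pr_s <- all_pairs_csd_power(lead_s, ci, X = NULL, method = "dual")
  nul_s <- null_coherence_volume(pr_s)
  expect_equal(nul_s$values[ok], nul$values[ok], tolerance = 1e-8)

  # orthogonal filters give zero null coherence: orthonormal synthetic gains
  g <- build_source_grid(0.03, 0.08)
  gsub <- g; gsub$positions <- g$positions[1:6, ]; gsub$n_dipoles <- 6L
  gsub$inside_mask <- rep(TRUE, 6)
  fake <- structure(list(gain = diag(12)[, 1:6], n_ori = 1L,
                         valid = rep(TRUE, 6), grid = gsub),
                    class = "leadfield")
  pr0 <- all_pairs_csd_power(fake, diag(12) + 0i, X = NULL, method = "dual",
                             min_distance = 0)
  nul0 <- null_coherence_volume(pr0, sigma = rep(1, 6))
  expect_lt(max(nul0$values[pr0$valid]), 1e-12)
})

test_that("corrected maps expose a planted interaction", {
  # subtract mode: coh = null gives a zero map
  vals <- matrix(runif(25), 5, 5); diag(vals) <- NA
  valid <- !is.na(vals)
  vol <- structure(list(values = vals, valid = valid, grid = NULL,
                        kind = "coherence"), class = "coherence_volume")
  nul <- structure(list(values = vals, valid = valid, grid = NULL,
                        kind = "null_coherence"), class = "coherence_volume")
  zero <- corrected_map(vol, nul, "subtract")
  expect_true(all(abs(zero$values[valid]) < 1e-12))

  # divide mode floors zero null entries and flags them
  nul2 <- nul; nul2$values[2, 1] <- 0
  div <- corrected_map(vol, nul2, "divide")
  expect_true(div$floored[2, 1])
  expect_true(is.finite(div$values[2, 1]))
  expect_error(corrected_map(vol, nul, "other"))

  # end-to-end: a planted pair at rho = 0.5 dominates the corrected map
  setup <- small_setup()
  sim <- simulate_dataset(setup$lead, setup$candidates, 0.5, pi / 3, 0.7, 0.8,
                          n_sources = 6, n_obs = 350, seed = 12)
  pp <- oriented_pipeline(setup, sim)
  pr <- all_pairs_csd_power(pp$lead, pp$ci, X = NULL, method = "dual",
                            distances = setup$distances)
  coh <- coherence_volume(pr)
  nul <- null_coherence_volume(pr, distances = setup$distances)
  cor <- corrected_map(coh, nul, "subtract")
  i <- sim$true_pair[1]; j <- sim$true_pair[2]
  expect_true(cor$valid[i, j])
  q99 <- stats::quantile(cor$values[cor$valid], 0.99, na.rm = TRUE)
  expect_gt(cor$values[i, j], q99)
})
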