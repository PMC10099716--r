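test_that("covariance of identical frames is zero; one frame is an error", {
  s <- free_atoms_structure(3)
  traj <- make_traj(s, replicate(5, s$coords, simplify = FALSE))
  cv <- mass_weighted_covariance(traj, 1:3)
  expect_equal(max(abs(cv)), 0)
  expect_error(mass_weighted_covariance(make_traj(s, list(s$coords)), 1:3),
               "insufficient data")
})

test_that("covariance matches closed-form second moments", {
  s <- free_atoms_structure(1, masses = 12)
  sigma <- 0.5
  set.seed(101)
  frames <- replicate(6000, s$coords + rnorm(3, sd = sigma),
                      simplify = FALSE)
  cv <- mass_weighted_covariance(make_traj(s, frames), 1)
  # diagonal ~ m sigma^2; eigen spread ~ sqrt(2/n)
  expect_equal(diag(cv), rep(12 * sigma^2, 3), tolerance = 0.1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 0.15 * 12 * sigma^2)

  # two perfectly correlated atoms: off-diagonal block sqrt(m1 m2) sigma^2
  s2 <- free_atoms_structure(2, masses = c(12, 16))
  set.seed(102)
  frames2 <- replicate(6000, {
    eps <- rnorm(3, sd = sigma)
    s2$coords + rbind(eps, eps)
  }, simplify = FALSE)
  cv2 <- mass_weighted_covariance(make_traj(s2, frames2), 1:2)
  block <- cv2[1:3, 4:6]
  expect_equal(diag(block), rep(sqrt(12 * 16) * sigma^2, 3),
               tolerance = 0.1)
  expect_true(isSymmetric(cv2))
  expect_gte(min(eigen(cv2, symmetric = TRUE)$values), -1e-10)
})

test_that("entropy formula matches the hand-evaluated oscillator sum", {
  lambda <- c(3, 1.5, 0.8)       # amu A^2
  cv <- diag(lambda)
  r <- quasi_harmonic_entropy(cv, temperature = 310)
  expect_equal(r$entropy, qho_entropy_oracle(lambda, 310),
               tolerance = 1e-10)
  expect_equal(r$n_modes_used, 3)
  expect_equal(r$n_modes_discarded, 0)

  # rigid body: zero covariance, everything floored, S = 0
  r0 <- quasi_harmonic_entropy(matrix(0, 6, 6), 310)
  expect_equal(r0$entropy, 0)
  expect_equal(r0$n_modes_discarded, 6)

  # softer modes (larger eigenvalues) carry more entropy
  r4 <- quasi_harmonic_entropy(diag(4 * lambda), 310)
  expect_gt(r4$entropy, r$entropy)

  expect_error(quasi_harmonic_entropy(matrix(1:9, 3, 3), 310), "symmetric")
})

test_that("entropy recovers the analytic value of a known Gaussian ensemble", {
  masses <- c(12.011, 14.007, 15.999, 12.011, 32.06)
  sigmas <- c(0.3, 0.5, 0.7, 0.4, 0.6)
  s <- free_atoms_structure(5, masses = masses)
  set.seed(103)
  frames <- replicate(6000, s$coords +
                        matrix(rnorm(15, sd = rep(sigmas, 3)), 5, 3),
                      simplify = FALSE)
  traj <- make_traj(s, frames)
  cv <- mass_weighted_covariance(traj, 1:5)
  est <- quasi_harmonic_entropy(cv, 310)
  truth <- qho_entropy_oracle(rep(masses * sigmas^2, each = 3), 310)
  expect_lt(abs(est$entropy - truth) / truth, 0.02)
  expect_equal(est$n_modes_used, 15)
})

test_that("entropy is invariant under a global rotation removed by superposition", {
  ref <- build_toy_dimer(89)
  core <- core_regions_from_helices(ref)
  traj <- sample_ensemble(ref, ensemble_recipe("restricted", n_frames = 300,
                                               seed = 19))
  sel <- which(ref$atoms$chain_id == "A" & ref$atoms$atom_name == "CA")
  R <- random_rotation()
  rotated <- make_traj(ref, lapply(traj$frames, function(fr)
    sweep(fr %*% t(R), 2, c(5, 5, 5), `+`)))
  e1 <- quasi_harmonic_entropy(mass_weighted_covariance(
    superpose_trajectory(traj, ref, core), sel), 310)
  e2 <- quasi_harmonic_entropy(mass_weighted_covariance(
    superpose_trajectory(rotated, ref, core), sel), 310)
  expect_equal(e1$entropy, e2$entropy, tolerance = 1e-6)
})

test_that("adding an independent fluctuating atom increases entropy", {
  s2 <- free_atoms_structure(2)
  set.seed(104)
  frames <- replicate(2000, s2$coords + matrix(rnorm(6, sd = 0.5), 2, 3),
                      simplify = FALSE)
  traj <- make_traj(s2, frames)
  s_one <- quasi_harmonic_entropy(mass_weighted_covariance(traj, 1), 310)
  s_two <- quasi_harmonic_entropy(mass_weighted_covariance(traj, 1:2), 310)
  expect_gt(s_two$entropy, s_one$entropy)
})

test_that("entropy convergence series levels off and validates checkpoints", {
  s <- free_atoms_structure(3)
  set.seed(105)
  frames <- replicate(3000, s$coords + matrix(rnorm(9, sd = 0.5), 3, 3),
                      simplify = FALSE)
  traj <- make_traj(s, frames)
  conv <- entropy_convergence(traj, 1:3, 310,
                              checkpoints = seq(500, 3000, by = 500))
  expect_equal(conv$n_frames, seq(500, 3000, by = 500))
  expect_true(attr(conv, "converged"))
  truth <- qho_entropy_oracle(rep(12.011 * 0.25, 9), 310)
  expect_lt(abs(conv$entropy[6] - truth) / truth, 0.02)
  # finite-sample covariance underestimates dispersion: approach from below
  expect_lt(conv$entropy[1], conv$entropy[6] + 1e-9)

  expect_error(entropy_convergence(traj, 1:3, 310,
                                   checkpoints = c(3000, 500)),
               "strictly increasing")
  expect_error(entropy_convergence(traj, 1:3, 310,
                                   checkpoints = c(500, 5000)),
               "exceeds")

  frozen <- make_traj(s, replicate(100, s$coords, simplify = FALSE))
  cz <- entropy_convergence(frozen, 1:3, 310, checkpoints = c(50, 100))
  expect_equal(cz$entropy, c(0, 0))
  expect_true(attr(cz, "converged"))
})
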