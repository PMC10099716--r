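test_that("superposing a set on itself is the identity", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  f <- kabsch_superpose(P, P)
  expect_equal(f$rotation, diag(3), tolerance = 1e-12)
  expect_equal(f$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(f$core_rmsd, 0, tolerance = 1e-12)
})

test_that("a known rigid motion is recovered exactly", {
  set.seed(2)
  P <- matrix(rnorm(30), 10, 3)
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- P %*% t(Rz) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  f <- kabsch_superpose(P, Q)
  expect_equal(f$rotation, Rz, tolerance = 1e-10)
  expect_lt(f$core_rmsd, 1e-10)
  expect_equal(det(f$rotation), 1, tolerance = 1e-8)
  aligned <- P %*% t(f$rotation) +
    matrix(f$translation, 10, 3, byrow = TRUE)
  expect_equal(aligned, Q, tolerance = 1e-10)
})

test_that("degenerate geometries are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)),
               "3 atom pairs")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("kabsch agrees with the quaternion oracle and minimises RMSD", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- sweep(P %*% t(random_rotation()), 2, rnorm(3, sd = 5), `+`) +
      matrix(rnorm(3 * n, sd = 0.5), n, 3)
    f <- kabsch_superpose(P, Q)
    expect_lt(abs(f$core_rmsd - horn_rmsd(P, Q)), 1e-9)
    naive <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(f$core_rmsd, naive + 1e-12)
  }
})

test_that("mass-style weights bias the fit toward heavy atoms", {
  set.seed(3)
  P <- matrix(rnorm(24), 8, 3)
  Q <- P
  Q[1, ] <- Q[1, ] + 5          # one outlier atom
  w <- c(0.001, rep(1, 7))
  fw <- kabsch_superpose(P, Q, weights = w)
  fu <- kabsch_superpose(P, Q)
  expect_lt(fw$core_rmsd, fu$core_rmsd)
})

test_that("region RMSD is zero on the reference and exact on a forced shift", {
  ref <- build_toy_dimer(89)
  core <- core_regions_from_helices(ref)
  traj <- make_traj(ref, list(ref$coords, ref$coords))
  s <- region_rmsd_series(traj, ref, core, region_spec("a1", "*", 5, 12),
                          discard_fraction = 0)
  expect_equal(s$rmsd, rep(0, 4), tolerance = 1e-10)

  shifted <- ref$coords
  idx <- which(ref$atoms$chain_id == "A" & ref$atoms$atom_name == "CA" &
                 ref$atoms$residue_number %in% 5:12)
  shifted[idx, 1] <- shifted[idx, 1] + 2
  s2 <- region_rmsd_series(make_traj(ref, list(shifted)), ref, core,
                           region_spec("a1", "A", 5, 12),
                           discard_fraction = 0)
  expect_equal(s2$rmsd, 2, tolerance = 1e-10)
})

test_that("region RMSD is invariant to rigid motion of a whole frame", {
  ref <- build_toy_dimer(89)
  core <- core_regions_from_helices(ref)
  rec <- ensemble_recipe("restricted", n_frames = 5, seed = 9)
  traj <- sample_ensemble(ref, rec)
  R <- random_rotation()
  moved <- lapply(traj$frames, function(fr)
    sweep(fr %*% t(R), 2, c(10, -4, 2), `+`))
  s1 <- region_rmsd_series(traj, ref, core, region_spec("a1", "*", 5, 12),
                           discard_fraction = 0)
  s2 <- region_rmsd_series(make_traj(ref, moved), ref, core,
                           region_spec("a1", "*", 5, 12),
                           discard_fraction = 0)
  expect_equal(s1$rmsd, s2$rmsd, tolerance = 1e-9)
})

test_that("distribution summary: density normalisation, median, modes", {
  set.seed(10)
  x <- c(rnorm(6000, 3, 0.4), rnorm(6000, 5, 0.4))
  d <- make_distribution(x, bin_width = 0.1)
  expect_equal(sum(d$density * diff(d$breaks)), 1, tolerance = 1e-6)
  expect_equal(d$median, median(x))
  expect_equal(nrow(d$modes), 2)
  expect_lt(abs(d$modes$location[1] - 3.0), 0.2)
  expect_lt(abs(d$modes$location[2] - 5.0), 0.2)

  u <- rnorm(6000, 3, 0.4)
  du <- make_distribution(u)
  expect_equal(nrow(du$modes), 1)
  expect_lt(abs(du$modes$location[1] - 3.0), 0.2)

  dc <- make_distribution(rep(2.5, 50))
  expect_equal(dc$median, 2.5)
  expect_equal(dc$modes$location, 2.5)

  expect_error(make_distribution(numeric(0)), "empty-data")
  expect_error(make_distribution(3), "empty-data")
})
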