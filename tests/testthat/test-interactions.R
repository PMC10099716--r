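# Small fixture: two chains, each with a 2-atom donor group (NH1/NH2 on
# residue 16) and a 1-atom acceptor (OXT on the terminal residue), whose
# coordinates the tests position by hand.
bridge_fixture <- function(donor_xyz, acceptor_xyz) {
  atoms <- data.frame(
    atom_name = c("NH1", "NH2", "OXT"),
    residue_name = c("ARG", "ARG", "LEU"),
    residue_number = c(16L, 16L, 89L),
    chain_id = c("A", "A", "B"),
    element = c("N", "N", "O"),
    mass = c(14.007, 14.007, 15.999), stringsAsFactors = FALSE)
  bafdyn:::new_structure_model(atoms, rbind(donor_xyz, acceptor_xyz))
}

donor_group <- list(chain = "A", residue_number = 16L,
                    atom_names = c("NH1", "NH2"))
acceptor_group <- list(chain = "B", residue_number = 89L,
                       atom_names = "OXT")
fixture_pair <- salt_bridge_pair(donor_group, acceptor_group)

test_that("bridge distance handles coincident and hand-placed groups", {
  s <- bridge_fixture(rbind(c(0, 0, 0), c(0, 0, 0)), c(0, 0, 0))
  expect_equal(bridge_distance(s, s$coords, fixture_pair), 0)

  s <- bridge_fixture(rbind(c(0, 0, 0), c(0, 0, 2)), c(0, 0, 5))
  expect_equal(bridge_distance(s, s$coords, fixture_pair,
                               "min-atom-pair"), 3.0)
  expect_equal(bridge_distance(s, s$coords, fixture_pair,
                               "group-centroid"), 4.0)
  expect_error(bridge_distance(s, s$coords, salt_bridge_pair(
    list(chain = "A", residue_number = 99L, atom_names = "XX"),
    acceptor_group)), "selection error")
})

test_that("min-atom-pair equals the brute-force all-pairs minimum", {
  set.seed(21)
  for (rep in 1:20) {
    D <- matrix(rnorm(15, sd = 3), 5, 3)
    A <- matrix(rnorm(15, sd = 3), 5, 3)
    atoms <- data.frame(
      atom_name = paste0("X", 1:10),
      residue_name = "GLY",
      residue_number = rep(c(1L, 2L), each = 5),
      chain_id = rep(c("A", "B"), each = 5),
      element = "C", mass = 12.011, stringsAsFactors = FALSE)
    s <- bafdyn:::new_structure_model(atoms, rbind(D, A))
    pair <- salt_bridge_pair(
      list(chain = "A", residue_number = 1L, atom_names = paste0("X", 1:5)),
      list(chain = "B", residue_number = 2L, atom_names = paste0("X", 6:10)))
    brute <- min(apply(D, 1, function(d)
      apply(A, 1, function(a) sqrt(sum((d - a)^2)))))
    expect_equal(bridge_distance(s, s$coords, pair), brute,
                 tolerance = 1e-12)
    # triangle-inequality bound against the centroid convention
    rad <- max(apply(D, 1, function(p) sqrt(sum((p - colMeans(D))^2))),
               apply(A, 1, function(p) sqrt(sum((p - colMeans(A))^2))))
    expect_lte(bridge_distance(s, s$coords, pair),
               bridge_distance(s, s$coords, pair, "group-centroid") +
                 2 * rad + 1e-12)
  }
})

test_that("occupancy counts frames below cutoff and is monotone in cutoff", {
  s <- bridge_fixture(rbind(c(0, 0, 0), c(0, 0, 0)), c(0, 0, 10))
  dists <- c(rep(3, 30), rep(7, 70))
  frames <- lapply(dists, function(d) {
    xyz <- s$coords
    xyz[3, ] <- c(0, 0, d)
    xyz
  })
  traj <- make_traj(s, frames)
  tr <- trace_bridge(traj, fixture_pair, cutoff = 4.0)
  expect_equal(unname(tr$occupancy["A->B"]), 0.30)
  occ <- vapply(c(1, 2.9, 3.1, 6.9, 7.1, 10),
                function(ct) trace_bridge(traj, fixture_pair,
                                          ct)$occupancy[["A->B"]],
                numeric(1))
  expect_true(all(diff(occ) >= 0))
  expect_equal(occ, c(0, 0, 0.3, 0.3, 1, 1))
})

test_that("enforced-bridge ensembles are occupied; unconstrained ones are not", {
  ref <- build_toy_dimer(89)
  g16r <- sample_ensemble(ref, ensemble_recipe("restricted", n_frames = 500,
                                               seed = 13))
  tr <- trace_bridge(g16r, toy_bridge_pair(ref), cutoff = 4.0)
  expect_true(all(tr$occupancy >= 0.95))

  wt <- sample_ensemble(ref, ensemble_recipe("open", n_frames = 500,
                                             seed = 13))
  tw <- trace_bridge(wt, toy_bridge_pair(ref), cutoff = 4.0)
  expect_true(all(tw$occupancy < 0.5))
})

test_that("scan_bridges finds enforced bridges, sorted, and respects cutoff", {
  ref <- build_toy_dimer(89)
  rec <- ensemble_recipe("restricted", n_frames = 1, seed = 2,
                         salt_bridge = list(target = 2.8,
                                            hold_probability = 1,
                                            orderings = "AB"))
  fr <- sample_ensemble(ref, rec)$frames[[1]]
  cterm <- 89L
  donors <- list(list(chain = "A", residue_number = 16L, atom_names = "NH1"),
                 list(chain = "B", residue_number = 16L, atom_names = "NH1"))
  acceptors <- list(list(chain = "A", residue_number = cterm,
                         atom_names = "OXT"),
                    list(chain = "B", residue_number = cterm,
                         atom_names = "OXT"))
  hits <- scan_bridges(ref, fr, donors, acceptors, cutoff = 4.0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$donor_chain, "A")
  expect_equal(hits$donor_residue, 16L)
  expect_equal(hits$acceptor_residue, cterm)
  expect_equal(hits$distance, 2.8, tolerance = 1e-9)

  expect_equal(nrow(scan_bridges(ref, fr, donors, acceptors, cutoff = 1.0)), 0)

  # two synthetic bridges at 2.5 and 3.5 A come back sorted ascending
  fr2 <- fr
  a_oxt <- which(ref$atoms$chain_id == "A" & ref$atoms$atom_name == "OXT")
  b_nh1 <- which(ref$atoms$chain_id == "B" & ref$atoms$atom_name == "NH1")
  a_nh1 <- which(ref$atoms$chain_id == "A" & ref$atoms$atom_name == "NH1")
  fr2[a_oxt, ] <- fr2[b_nh1, ] + c(3.5, 0, 0)
  fr2[which(ref$atoms$chain_id == "B" & ref$atoms$atom_name == "OXT"), ] <-
    fr2[a_nh1, ] + c(2.5, 0, 0)
  hits2 <- scan_bridges(ref, fr2, donors, acceptors, cutoff = 4.0)
  expect_equal(nrow(hits2), 2)
  expect_equal(hits2$distance, c(2.5, 3.5), tolerance = 1e-9)
})
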