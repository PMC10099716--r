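# Independent oracles and small fixture builders shared across test files.
# Each oracle is a deliberately separate code path from the implementation
# it checks.

# Horn's quaternion method for least-squares superposition: largest
# eigenvector of the 4x4 profile matrix built from the cross-covariance.
# Returns the optimal RMSD between mobile and target (unit weights).
horn_rmsd <- function(mobile, target) {
  n <- nrow(mobile)
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda_max <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(P^2) + sum(Q^2) - 2 * lambda_max
  sqrt(max(0, ss) / n)
}

# Quantum harmonic oscillator entropy per mode, evaluated directly from
# hand-typed CODATA constants (cal/mol/K). lambda in amu A^2.
qho_entropy_oracle <- function(lambda, temperature) {
  kB <- 1.380649e-23; hbar <- 1.054571817e-34
  amu <- 1.66053906660e-27; Rcal <- 8.31446261815324 / 4.184
  s <- 0
  for (lam in lambda) {
    u <- hbar / sqrt(kB * temperature * lam * amu * 1e-20)
    s <- s + u / (exp(u) - 1) - log(1 - exp(-u))
  }
  Rcal * s
}

# A tiny handwritten 3-atom PDB (fixed wwPDB columns) with a HELIX record.
toy_pdb_text <- function() {
  c("HELIX    1   1 GLY A    2  GLY A    3  1                                   2",
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       2.500  -1.250   0.125  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2      -3.000   4.000   5.500  1.00  0.00           C",
    "END")
}

# Per-residue C-alpha toy chain: one CA per residue on a line.
toy_chain_structure <- function(n_res = 89, chain = "A") {
  atoms <- data.frame(
    atom_name = "CA", residue_name = "GLY",
    residue_number = seq_len(n_res), chain_id = chain, element = "C",
    mass = 12.011, stringsAsFactors = FALSE)
  coords <- cbind(x = 3.8 * seq_len(n_res), y = 0, z = 0)
  bafdyn:::new_structure_model(atoms, coords)
}

# Structure of n free atoms (mass 12.011 C) for entropy fixtures.
free_atoms_structure <- function(n_atoms, masses = rep(12.011, n_atoms)) {
  atoms <- data.frame(
    atom_name = "CA", residue_name = "GLY",
    residue_number = seq_len(n_atoms), chain_id = "A",
    element = "C", mass = masses, stringsAsFactors = FALSE)
  bafdyn:::new_structure_model(atoms, cbind(seq_len(n_atoms) * 4, 0, 0))
}

make_traj <- function(topology, frames) {
  bafdyn:::new_trajectory_ensemble(topology, frames)
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
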