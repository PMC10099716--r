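#' Mass-weighted covariance of superposed fluctuations
#'
#' Builds the 3N x 3N mass-weighted Cartesian covariance matrix
#' `C[i,j] = sqrt(m_i m_j) <dx_i dx_j>`, with deviations taken from the
#' ensemble mean, over a selected atom set. Frames must already be
#' superposed on the reference core (see [superpose_trajectory()]): the
#' quasi-harmonic treatment assumes overall rotation and translation have
#' been removed, leaving ~6 near-null modes that the entropy step floors
#' out.
#'
#' @param traj A `trajectory_ensemble` with superposed frames.
#' @param selection Integer atom indices (e.g. one monomer's C-alphas).
#' @return Symmetric positive semi-definite matrix, units amu Angstrom^2.
#' @export
mass_weighted_covariance <- function(traj, selection) {
  stopifnot(inherits(traj, "trajectory_ensemble"), length(selection) >= 1)
  nf <- n_frames(traj)
  if (nf < 2) stop("insufficient data: need >= 2 frames for a covariance")
  X <- t(vapply(traj$frames, function(fr)
    as.numeric(t(fr[selection, , drop = FALSE])), numeric(3 * length(selection))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nf
  m <- rep(traj$topology$atoms$mass[selection], each = 3)
  sq <- sqrt(m)
  C <- C * tcrossprod(sq)
  (C + t(C)) / 2
}

#' Quasi-harmonic configurational entropy
#'
#' Diagonalises the mass-weighted covariance and treats each retained
#' eigenmode as a quantum harmonic oscillator of frequency
#' `omega_i = sqrt(kB T / lambda_i)`. The molar entropy is
#' `S = R * sum_i [ u_i / (exp(u_i) - 1) - log(1 - exp(-u_i)) ]` with
#' `u_i = hbar omega_i / (kB T)`. Small eigenvalues (at or below the floor)
#' are the rigid-body modes nulled by superposition; they are discarded and
#' counted, never silently dropped. Constants are CODATA 2018
#' ([baf_constants]).
#'
#' @param cov Symmetric PSD matrix from [mass_weighted_covariance()],
#'   amu Angstrom^2.
#' @param temperature Kelvin; default 310, the simulation thermostat.
#' @param eigenvalue_floor amu Angstrom^2; modes with eigenvalue at or
#'   below it are discarded (default 1e-8).
#' @return An `entropy_result`: `eigenvalues` (all, descending),
#'   `frequencies` (rad/s, retained modes), `temperature`, `entropy`
#'   (cal mol^-1 K^-1), `n_modes_used`, `n_modes_discarded`.
#' @export
quasi_harmonic_entropy <- function(cov, temperature = 310,
                                   eigenvalue_floor = 1e-8) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  if (temperature <= 0) stop("temperature must be positive")
  lambda <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(lambda < -1e-10 * max(1, max(abs(lambda)))))
    stop("covariance is not positive semi-definite (eigenvalue ",
         format(min(lambda)), ")")
  keep <- lambda > eigenvalue_floor
  lam <- lambda[keep]
  const <- baf_constants
  # lambda in amu A^2 -> SI kg m^2
  lam_si <- lam * const$amu * 1e-20
  omega <- sqrt(const$kB * temperature / lam_si)
  u <- const$hbar * omega / (const$kB * temperature)
  s_modes <- u / (exp(u) - 1) - log(1 - exp(-u))
  entropy <- const$R_cal * sum(s_modes)
  if (length(lam) == 0) entropy <- 0
  structure(list(eigenvalues = lambda,
                 frequencies = if (length(lam)) omega else numeric(0),
                 temperature = temperature,
                 entropy = entropy,
                 n_modes_used = sum(keep),
                 n_modes_discarded = sum(!keep),
                 eigenvalue_floor = eigenvalue_floor,
                 constants = const),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(paste0("entropy_result: S = %.2f cal/mol/K at %g K ",
                     "(%d modes used, %d discarded)\n"),
              x$entropy, x$temperature, x$n_modes_used, x$n_modes_discarded))
  invisible(x)
}

#' Entropy as a function of sampling (convergence check)
#'
#' Recomputes the quasi-harmonic entropy on the first `k` frames for each
#' checkpoint, mirroring the completeness-of-sampling check: the entropy is
#' plotted against simulation time and must level off. The series is
#' flagged converged when the last two checkpoints differ by less than
#' `tol` relative.
#'
#' @inheritParams mass_weighted_covariance
#' @param temperature Kelvin.
#' @param checkpoints Strictly increasing frame counts, max at most the
#'   trajectory length.
#' @param eigenvalue_floor Passed to [quasi_harmonic_entropy()].
#' @param tol Relative convergence tolerance between the last two
#'   checkpoints (default 0.01).
#' @return data.frame `n_frames`, `entropy`, with attribute `converged`.
#' @export
entropy_convergence <- function(traj, selection, temperature = 310,
                                checkpoints = NULL,
                                eigenvalue_floor = 1e-8, tol = 0.01) {
  nf <- n_frames(traj)
  if (is.null(checkpoints))
    checkpoints <- unique(round(seq(nf / 12, nf, length.out = 12)))
  if (any(diff(checkpoints) <= 0))
    stop("checkpoints must be strictly increasing")
  if (max(checkpoints) > nf)
    stop("checkpoint exceeds trajectory length")
  if (min(checkpoints) < 2) stop("checkpoints must be >= 2 frames")
  ent <- vapply(checkpoints, function(k) {
    sub <- new_trajectory_ensemble(traj$topology, traj$frames[seq_len(k)])
    cv <- mass_weighted_covariance(sub, selection)
    quasi_harmonic_entropy(cv, temperature, eigenvalue_floor)$entropy
  }, numeric(1))
  last2 <- ent[length(ent) - c(1, 0)]
  denom <- max(abs(last2[2]), .Machine$double.eps)
  converged <- abs(last2[2] - last2[1]) / denom < tol
  out <- data.frame(n_frames = checkpoints, entropy = ent)
  attr(out, "converged") <- converged
  out
}
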