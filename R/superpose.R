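#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two matched coordinate sets, via SVD of the
#' weighted cross-covariance with reflection-branch correction. This is the
#' superposition used throughout: frames are fitted on the C-alpha positions
#' of the rigid core helices before any region RMSD or covariance analysis,
#' which removes overall rotation and translation.
#'
#' @param mobile,target N x 3 coordinate matrices (Angstrom), row-matched.
#' @param weights Optional non-negative per-atom weights; default unit
#'   weights (plain C-alpha RMSD, no mass weighting).
#' @return A `superposition_result`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), and `core_rmsd` (Angstrom). The aligned
#'   mobile set is `mobile %*% t(rotation) + translation` (rows as points).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3)
    stop("mobile and target must be matched N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("degenerate geometry: need >= 3 atom pairs")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  # collinearity check on the weighted mobile set
  if (min(svd(P * sqrt(w))$d) < 1e-10 * max(1, max(abs(P))))
    stop("degenerate geometry: atom set is (near-)collinear")
  A <- t(P * w) %*% Q                      # 3 x 3 cross-covariance
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # column-vector convention
  aligned <- P %*% t(R)
  core_rmsd <- sqrt(sum(w * rowSums((aligned - Q)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(ct - R %*% cm),
                 core_rmsd = core_rmsd),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition_result: core RMSD %.4f A\n", x$core_rmsd))
  invisible(x)
}

.apply_superposition <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Per-frame, per-monomer region RMSD
#'
#' For every frame and every chain, the chain is superposed onto the
#' reference using the core C-alpha atoms only (helices alpha-3 to alpha-6
#' by default); the RMSD is then computed over the region C-alpha atoms
#' without re-fitting. Chains are treated independently, so an `n`-frame
#' dimer trajectory yields `2n` monomeric RMSD values, matching the pooled
#' monomeric-structure analysis. A leading fraction of frames can be
#' discarded as equilibration.
#'
#' @param traj A `trajectory_ensemble`.
#' @param ref Reference `structure_model` (same topology).
#' @param core List of [region_spec()] defining the superposition core, or
#'   `NULL` to derive it from the reference HELIX records
#'   ([core_regions_from_helices()]).
#' @param region A [region_spec()] with `chain_id = NA`/`"*"` meaning "this
#'   residue window on every chain", or a single-chain region.
#' @param discard_fraction Leading fraction of frames dropped before
#'   analysis (equilibration discard), default 0.02.
#' @return A data.frame with columns `frame`, `chain`, `rmsd` (Angstrom).
#' @export
region_rmsd_series <- function(traj, ref, core = NULL, region,
                               discard_fraction = 0.02) {
  stopifnot(inherits(traj, "trajectory_ensemble"),
            inherits(ref, "structure_model"))
  if (is.null(core)) core <- core_regions_from_helices(ref)
  if (inherits(core, "region_spec")) core <- list(core)
  chains <- sort(unique(ref$atoms$chain_id))
  target_chains <- if (is.na(region$chain_id) || region$chain_id == "*")
    chains else region$chain_id
  nf <- n_frames(traj)
  keep <- seq_len(nf)
  n_drop <- floor(discard_fraction * nf)
  if (n_drop > 0) keep <- keep[-seq_len(n_drop)]

  out <- vector("list", length(target_chains))
  for (ci in seq_along(target_chains)) {
    ch <- target_chains[ci]
    core_ch <- lapply(core[vapply(core, function(r) r$chain_id == ch,
                                  logical(1))],
                      identity)
    if (length(core_ch) == 0)
      stop("no core regions defined for chain ", ch)
    core_idx <- select_calpha(ref, core_ch)
    reg_idx <- select_calpha(ref, region_spec(region$name, ch,
                                              region$start, region$end))
    ref_core <- ref$coords[core_idx, , drop = FALSE]
    ref_reg <- ref$coords[reg_idx, , drop = FALSE]
    vals <- vapply(keep, function(f) {
      fr <- traj$frames[[f]]
      fit <- kabsch_superpose(fr[core_idx, , drop = FALSE], ref_core)
      reg <- .apply_superposition(fr[reg_idx, , drop = FALSE], fit)
      sqrt(mean(rowSums((reg - ref_reg)^2)))
    }, numeric(1))
    out[[ci]] <- data.frame(frame = keep, chain = ch, rmsd = vals,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Superpose every frame onto a reference core
#'
#' Returns a trajectory whose frames are rigid-body fitted, per chain, onto
#' the reference core C-alpha atoms. This is the prerequisite for the
#' quasi-harmonic covariance analysis (overall rotation and translation
#' removed).
#'
#' @inheritParams region_rmsd_series
#' @param chain Chain to superpose and retain, or `NULL` to fit each chain
#'   in place and keep the full topology.
#' @return A `trajectory_ensemble` with fitted coordinates.
#' @export
superpose_trajectory <- function(traj, ref, core = NULL, chain = NULL) {
  if (is.null(core)) core <- core_regions_from_helices(ref)
  chains <- if (is.null(chain)) sort(unique(ref$atoms$chain_id)) else chain
  frames <- traj$frames
  for (ch in chains) {
    core_ch <- core[vapply(core, function(r) r$chain_id == ch, logical(1))]
    if (length(core_ch) == 0) stop("no core regions defined for chain ", ch)
    core_idx <- select_calpha(ref, core_ch)
    ch_idx <- which(ref$atoms$chain_id == ch)
    ref_core <- ref$coords[core_idx, , drop = FALSE]
    for (f in seq_along(frames)) {
      fit <- kabsch_superpose(frames[[f]][core_idx, , drop = FALSE], ref_core)
      frames[[f]][ch_idx, ] <- .apply_superposition(
        frames[[f]][ch_idx, , drop = FALSE], fit)
    }
  }
  new_trajectory_ensemble(traj$topology, frames, traj$frame_times)
}
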