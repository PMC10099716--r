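.group_atoms <- function(atoms, group) {
  idx <- which(atoms$chain_id == group$chain &
                 atoms$residue_number == group$residue_number &
                 atoms$atom_name %in% group$atom_names)
  if (length(idx) == 0)
    stop("selection error: no atoms for group chain ", group$chain,
         " residue ", group$residue_number, " (",
         paste(group$atom_names, collapse = ","), ")", call. = FALSE)
  idx
}

#' Donor-acceptor distance of a salt-bridge pair in one frame
#'
#' Scores the electrostatic contact between a charged donor group (e.g. the
#' arginine guanidinium nitrogens) and an acceptor group (e.g. C-terminal
#' carboxylate oxygens). `"min-atom-pair"` (default) takes the minimum over
#' all donor-atom x acceptor-atom distances, which is robust to guanidinium
#' symmetry; `"group-centroid"` uses the distance between group centroids.
#'
#' @param structure `structure_model` providing the atom table.
#' @param coords Frame coordinates (N x 3), matched to the atom table.
#' @param pair A [salt_bridge_pair()].
#' @param method `"min-atom-pair"` or `"group-centroid"`.
#' @return Distance in Angstrom.
#' @export
bridge_distance <- function(structure, coords, pair,
                            method = c("min-atom-pair", "group-centroid")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  di <- .group_atoms(structure$atoms, pair$donor)
  ai <- .group_atoms(structure$atoms, pair$acceptor)
  D <- coords[di, , drop = FALSE]
  A <- coords[ai, , drop = FALSE]
  if (method == "group-centroid") {
    sqrt(sum((colMeans(D) - colMeans(A))^2))
  } else {
    d2 <- outer(rowSums(D^2), rowSums(A^2), `+`) - 2 * D %*% t(A)
    sqrt(max(0, min(d2)))
  }
}

#' Trace a salt bridge along a trajectory
#'
#' Computes the donor-acceptor distance in every frame, for both chain
#' orderings independently (A-donor to B-acceptor and B-donor to
#' A-acceptor, as the dimer is symmetric), and scores occupancy as the
#' fraction of frames with distance at or below the cutoff. A bridge is
#' conventionally reported "stable" when occupancy is at least 0.9.
#'
#' @param traj A `trajectory_ensemble`.
#' @param pair A [salt_bridge_pair()]; the swapped-chain ordering is derived
#'   from it automatically.
#' @param cutoff Formation cutoff in Angstrom; default 4.0 (standard
#'   donor-N to acceptor-O salt-bridge criterion).
#' @param method Distance convention, see [bridge_distance()].
#' @return A `salt_bridge_trace`: per-ordering data.frame `distances`
#'   (columns `frame`, `ordering`, `distance`), `occupancy` (named numeric,
#'   one entry per ordering), `cutoff`, `method`.
#' @export
trace_bridge <- function(traj, pair, cutoff = 4.0,
                         method = c("min-atom-pair", "group-centroid")) {
  method <- match.arg(method)
  swapped <- salt_bridge_pair(
    donor = utils::modifyList(pair$donor, list(chain = pair$acceptor$chain)),
    acceptor = utils::modifyList(pair$acceptor,
                                 list(chain = pair$donor$chain)))
  orderings <- list(pair)
  # the swapped ordering only exists when the partner chain carries the
  # same groups (symmetric homodimer); skip it otherwise
  resolves <- tryCatch({
    .group_atoms(traj$topology$atoms, swapped$donor)
    .group_atoms(traj$topology$atoms, swapped$acceptor)
    TRUE
  }, error = function(e) FALSE)
  if (resolves) orderings <- c(orderings, list(swapped))
  labels <- vapply(orderings, function(p)
    paste0(p$donor$chain, "->", p$acceptor$chain), character(1))
  nf <- n_frames(traj)
  res <- lapply(seq_along(orderings), function(k) {
    d <- vapply(seq_len(nf), function(f)
      bridge_distance(traj$topology, traj$frames[[f]], orderings[[k]],
                      method),
      numeric(1))
    data.frame(frame = seq_len(nf), ordering = labels[k], distance = d,
               stringsAsFactors = FALSE)
  })
  distances <- do.call(rbind, res)
  occupancy <- vapply(res, function(x) mean(x$distance <= cutoff),
                      numeric(1))
  names(occupancy) <- labels
  structure(list(pair = pair, distances = distances,
                 occupancy = occupancy, cutoff = cutoff, method = method),
            class = "salt_bridge_trace")
}

#' @export
print.salt_bridge_trace <- function(x, ...) {
  cat(sprintf("salt_bridge_trace (%s, cutoff %.1f A): occupancy %s\n",
              x$method, x$cutoff,
              paste(sprintf("%s %.3f", names(x$occupancy), x$occupancy),
                    collapse = ", ")))
  invisible(x)
}

#' Scan a frame for inter-chain salt bridges
#'
#' Evaluates every inter-chain donor-group x acceptor-group combination and
#' returns those whose min-atom-pair distance is at or below the cutoff,
#' sorted ascending by distance. Used to discover bridges (such as the
#' Arg16 guanidinium to partner-chain Leu89 carboxylate contact) rather
#' than trace a known one.
#'
#' @param structure `structure_model` providing the atom table.
#' @param coords Frame coordinates (N x 3).
#' @param donors,acceptors Lists of groups (`chain`, `residue_number`,
#'   `atom_names`).
#' @param cutoff Angstrom; default 4.0.
#' @return data.frame with `donor_chain`, `donor_residue`, `acceptor_chain`,
#'   `acceptor_residue`, `distance`, possibly empty.
#' @export
scan_bridges <- function(structure, coords, donors, acceptors,
                         cutoff = 4.0) {
  stopifnot(length(donors) >= 1, length(acceptors) >= 1)
  hits <- list()
  for (d in donors) for (a in acceptors) {
    if (d$chain == a$chain) next
    dist <- bridge_distance(structure, coords,
                            salt_bridge_pair(d, a), "min-atom-pair")
    if (dist <= cutoff)
      hits[[length(hits) + 1L]] <- data.frame(
        donor_chain = d$chain, donor_residue = d$residue_number,
        acceptor_chain = a$chain, acceptor_residue = a$residue_number,
        distance = dist, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(donor_chain = character(0),
                      donor_residue = integer(0),
                      acceptor_chain = character(0),
                      acceptor_residue = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$distance), , drop = FALSE]
}
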