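#' @title Structure and trajectory containers
#' @name structures
#' @description
#' The package represents a protein structure as a `structure_model`: an
#' ordered atom table (name, residue name/number, chain, element, mass) plus
#' an N x 3 coordinate matrix in Angstrom, and optionally the helix spans
#' parsed from HELIX records. A `trajectory_ensemble` is an ordered list of
#' coordinate frames sharing one topology, with optional frame times in ns.
#' Residue numbering is 1-based and chain-qualified throughout, because the
#' analyte is a homodimer.
NULL

new_structure_model <- function(atoms, coords, helices = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  coords <- as.matrix(coords)
  stopifnot(is.numeric(coords), ncol(coords) == 3)
  if (nrow(atoms) != nrow(coords))
    stop("coords length (", nrow(coords), ") != atom count (", nrow(atoms), ")")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in structure")
  if (any(atoms$residue_number < 1))
    stop("residue numbers must be >= 1")
  if (any(atoms$mass <= 0))
    stop("atom masses must be positive")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords, helices = helices),
            class = "structure_model")
}

new_trajectory_ensemble <- function(topology, frames, frame_times = NULL) {
  stopifnot(inherits(topology, "structure_model"), is.list(frames))
  n_atoms <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != n_atoms)
      stop("frame ", i, " has ", nrow(frames[[i]]), " atoms; topology has ",
           n_atoms)
  }
  if (!is.null(frame_times)) {
    if (length(frame_times) != length(frames))
      stop("frame_times length != number of frames")
    if (any(diff(frame_times) <= 0))
      stop("frame_times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames,
                 frame_times = frame_times),
            class = "trajectory_ensemble")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain_id)), "chain(s)")
  if (!is.null(x$helices) && nrow(x$helices) > 0)
    cat(",", nrow(x$helices), "helix record(s)")
  cat("\n")
  invisible(x)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble:", length(x$frames), "frames x",
      nrow(x$topology$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

.guess_element <- function(atom_name) {
  # PDB convention: element is right-justified in cols 77-78; when absent,
  # infer from the atom name (two-letter elements like SE/FE are rare here).
  nm <- gsub("[^A-Za-z].*$", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "CL"), two,
         toupper(substr(nm, 1, 1)))
}

.parse_atom_lines <- function(lines, line_numbers) {
  field <- function(a, b) substr(lines, a, b)
  num_field <- function(a, b, what) {
    raw <- field(a, b)
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !grepl("^\\s*$", raw) | is.na(v))
    if (length(bad) > 0)
      stop("PDB parse error at line ", line_numbers[bad[1]],
           ": non-numeric ", what, " field '", trimws(raw[bad[1]]), "'",
           call. = FALSE)
    v
  }
  atom_name <- trimws(field(13, 16))
  residue_name <- trimws(field(18, 20))
  chain_id <- field(22, 22)
  residue_number <- num_field(23, 26, "residue-number")
  x <- num_field(31, 38, "x")
  y <- num_field(39, 46, "y")
  z <- num_field(47, 54, "z")
  element <- trimws(field(77, 78))
  element <- ifelse(element == "", .guess_element(atom_name), toupper(element))
  atoms <- data.frame(
    atom_name = atom_name, residue_name = residue_name,
    residue_number = as.integer(residue_number), chain_id = chain_id,
    element = element, stringsAsFactors = FALSE)
  atoms$mass <- element_mass(atoms$element)
  list(atoms = atoms, coords = cbind(x = x, y = y, z = z))
}

.parse_helix_lines <- function(lines) {
  if (length(lines) == 0) return(NULL)
  data.frame(
    chain_id = substr(lines, 20, 20),
    start = as.integer(substr(lines, 22, 25)),
    end = as.integer(substr(lines, 34, 37)),
    stringsAsFactors = FALSE)
}

#' Read a PDB structure file
#'
#' Parses ATOM/HETATM records (fixed wwPDB columns) into a
#' `structure_model`. HELIX records, when present, are parsed into
#' chain-qualified `(start, end)` residue spans. Masses are assigned from
#' the element column (or inferred from the atom name when the column is
#' blank). For multi-model files only the first model is read; use
#' [read_trajectory()] for frame streams.
#'
#' @param path Path to a PDB file.
#' @return A `structure_model`.
#' @seealso [write_pdb()], [read_trajectory()]
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  endmdl <- which(trimws(rec) == "ENDMDL")
  last <- if (length(endmdl) > 0) endmdl[1] else length(lines)
  in_model <- seq_len(last)
  is_atom <- in_model[trimws(rec[in_model]) %in% c("ATOM", "HETATM")]
  if (length(is_atom) == 0)
    stop("empty structure: no ATOM records in ", path)
  parsed <- .parse_atom_lines(lines[is_atom], is_atom)
  helices <- .parse_helix_lines(lines[trimws(rec) == "HELIX"])
  new_structure_model(parsed$atoms, parsed$coords, helices)
}

.format_atom_lines <- function(atoms, coords) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          seq_len(nrow(atoms)),
          ifelse(nchar(atoms$atom_name) < 4,
                 paste0(" ", atoms$atom_name), atoms$atom_name),
          atoms$residue_name, atoms$chain_id, atoms$residue_number,
          coords[, 1], coords[, 2], coords[, 3], atoms$element)
}

#' Write a structure or trajectory as PDB
#'
#' Coordinates are written at the PDB fixed-column precision (3 decimals,
#' Angstrom), so `read_pdb(write_pdb(x))` round-trips coordinates to 1e-3.
#' A `trajectory_ensemble` is written as a multi-model PDB
#' (MODEL/ENDMDL-delimited frames).
#'
#' @param x A `structure_model` or `trajectory_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hel <- if (inherits(x, "structure_model")) x$helices else x$topology$helices
  if (!is.null(hel) && nrow(hel) > 0) {
    writeLines(sprintf(
      "HELIX  %3d %3s GLY %1s %4d  GLY %1s %4d  1%36d",
      seq_len(nrow(hel)), sprintf("%3d", seq_len(nrow(hel))),
      hel$chain_id, hel$start, hel$chain_id, hel$end,
      hel$end - hel$start + 1L), con)
  }
  if (inherits(x, "structure_model")) {
    writeLines(.format_atom_lines(x$atoms, x$coords), con)
    writeLines("END", con)
  } else if (inherits(x, "trajectory_ensemble")) {
    for (i in seq_along(x$frames)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(.format_atom_lines(x$topology$atoms, x$frames[[i]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop("x must be a structure_model or trajectory_ensemble")
  invisible(path)
}

.read_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  model_starts <- which(rec == "MODEL")
  if (length(model_starts) == 0) {
    s <- read_pdb(path)
    return(new_trajectory_ensemble(s, list(s$coords)))
  }
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  helices <- .parse_helix_lines(lines[rec == "HELIX"])
  topology <- NULL
  frames <- vector("list", length(model_starts))
  for (i in seq_along(model_starts)) {
    span <- seq(model_starts[i] + 1L, model_ends[i] - 1L)
    atom_idx <- span[rec[span] %in% c("ATOM", "HETATM")]
    parsed <- .parse_atom_lines(lines[atom_idx], atom_idx)
    if (is.null(topology)) {
      topology <- new_structure_model(parsed$atoms, parsed$coords, helices)
    } else if (nrow(parsed$coords) != nrow(topology$atoms)) {
      stop("inconsistent atom count in frame ", i, ": ",
           nrow(parsed$coords), " vs ", nrow(topology$atoms),
           " in frame 1", call. = FALSE)
    }
    frames[[i]] <- parsed$coords
  }
  new_trajectory_ensemble(topology, frames)
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames <- list()
  topology <- NULL
  frame_i <- 0L
  while (pos <= length(lines)) {
    if (grepl("^\\s*$", lines[pos])) { pos <- pos + 1L; next }
    frame_i <- frame_i + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1)
      stop("XYZ parse error at line ", pos, ": expected atom count")
    if (pos + 1L + n > length(lines))
      stop("truncated XYZ frame ", frame_i, " at line ", pos)
    rows <- strsplit(trimws(lines[(pos + 2L):(pos + 1L + n)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop("XYZ parse error in frame ", frame_i, ": need 'element x y z' rows")
    el <- vapply(rows, `[[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("XYZ parse error in frame ", frame_i, ": non-numeric coordinate")
    if (is.null(topology)) {
      atoms <- data.frame(
        atom_name = el, residue_name = "UNK",
        residue_number = seq_len(n), chain_id = "A",
        element = toupper(el), stringsAsFactors = FALSE)
      atoms$mass <- element_mass(atoms$element)
      topology <- new_structure_model(atoms, xyz)
    } else if (n != nrow(topology$atoms)) {
      stop("inconsistent atom count in frame ", frame_i, ": ", n, " vs ",
           nrow(topology$atoms), " in frame 1", call. = FALSE)
    }
    frames[[frame_i]] <- xyz
    pos <- pos + 2L + n
  }
  if (length(frames) == 0) stop("no frames found in ", path)
  new_trajectory_ensemble(topology, frames)
}

#' Read a coordinate trajectory
#'
#' Reads an ordered frame stream into a `trajectory_ensemble`. Two plain-text
#' dialects are supported: multi-model PDB (MODEL/ENDMDL) and XYZ frame
#' streams (atom-count line, comment line, then `element x y z` rows per
#' frame). The topology is taken from the first frame; an inconsistent atom
#' count in a later frame is an error naming that frame.
#'
#' @param path Path to the trajectory file.
#' @param format `"multi-model-pdb"` or `"xyz-frames"`.
#' @return A `trajectory_ensemble`.
#' @export
read_trajectory <- function(path, format = c("multi-model-pdb", "xyz-frames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "multi-model-pdb" = .read_multimodel_pdb(path),
         "xyz-frames" = .read_xyz_frames(path))
}

#' Define a chain-qualified residue region
#'
#' Regions name the residue windows the analysis operates on: the
#' always-flexible N-terminus (residues 1-4), the transiently folded helix
#' alpha-1 (residues 5-12), the full N-terminal arm (1-12), and the
#' superposition core (helices alpha-3 to alpha-6).
#'
#' @param name Region label used in outputs and error messages.
#' @param chain_id Single chain character.
#' @param start,end Inclusive 1-based residue bounds, `start <= end`.
#' @return A `region_spec`.
#' @export
region_spec <- function(name, chain_id, start, end) {
  stopifnot(is.character(name), nchar(chain_id) == 1)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid region '", name, "': need start <= end")
  structure(list(name = name, chain_id = chain_id,
                 start = start, end = end),
            class = "region_spec")
}

#' Select C-alpha atoms for one or more regions
#'
#' Resolves regions to C-alpha atom indices in a structure or trajectory
#' topology. Indices are sorted by (chain, residue number), deduplicated,
#' and each residue contributes at most one atom. Selection is idempotent:
#' reapplying a region to the selected subset returns the same atoms.
#'
#' @param x A `structure_model` or `trajectory_ensemble`.
#' @param regions A `region_spec` or list of them.
#' @return Integer vector of atom indices into the atom table.
#' @export
select_calpha <- function(x, regions) {
  atoms <- if (inherits(x, "trajectory_ensemble")) x$topology$atoms else x$atoms
  if (inherits(regions, "region_spec")) regions <- list(regions)
  idx <- integer(0)
  for (rg in regions) {
    hit <- which(atoms$atom_name == "CA" &
                   atoms$chain_id == rg$chain_id &
                   atoms$residue_number >= rg$start &
                   atoms$residue_number <= rg$end)
    if (length(hit) == 0)
      stop("selection error: region '", rg$name, "' (chain ", rg$chain_id,
           ", residues ", rg$start, "-", rg$end, ") matches no C-alpha atom",
           call. = FALSE)
    # one atom per residue (first CA wins if duplicated, e.g. altlocs)
    hit <- hit[!duplicated(atoms$residue_number[hit])]
    idx <- c(idx, hit)
  }
  idx <- unique(idx)
  idx[order(atoms$chain_id[idx], atoms$residue_number[idx])]
}

#' Default superposition core from HELIX records
#'
#' The core used for superposition is the rigid helical bundle (helices
#' alpha-3 to alpha-6). The reference structure's HELIX records define it:
#' for each chain the last four helix spans are taken. An explicit list of
#' [region_spec()] can always be supplied instead.
#'
#' @param ref A `structure_model` with a non-empty `helices` table.
#' @return List of `region_spec`, one per (chain, helix).
#' @export
core_regions_from_helices <- function(ref) {
  hel <- ref$helices
  if (is.null(hel) || nrow(hel) == 0)
    stop("reference structure has no HELIX records; supply core regions explicitly")
  out <- list()
  for (ch in unique(hel$chain_id)) {
    h <- hel[hel$chain_id == ch, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    if (nrow(h) < 4)
      stop("chain ", ch, " has fewer than 4 helices; supply core regions explicitly")
    h <- utils::tail(h, 4)
    for (k in seq_len(nrow(h)))
      out[[length(out) + 1L]] <- region_spec(
        paste0("core_", ch, "_", k), ch, h$start[k], h$end[k])
  }
  out
}
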