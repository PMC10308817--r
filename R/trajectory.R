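#' Trajectory container
#'
#' A light container for a multi-frame coordinate trajectory: a
#' `frames x atoms x 3` coordinate array (Å) plus an atom table. Atom indices
#' used throughout the package are 1-based row numbers of the atom table;
#' PDB serials are carried in the `serial` column and preserved on file
#' round-trips.
#'
#' @param coords Numeric array `[n_frames, n_atoms, 3]`, or a single
#'   `n_atoms x 3` matrix for a one-frame "trajectory".
#' @param atoms Data frame with one row per atom. Recognised columns:
#'   `serial`, `name`, `element`, `resname`, `resid`, `molecule` (one of
#'   `"receptor"`, `"ligand"`, `"water"`, `"other"`). Missing columns are
#'   filled with defaults (`element` is derived from the first letter of
#'   `name` when absent).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, atoms = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n_atoms <- dim(coords)[2]
  if (is.null(atoms)) atoms <- tibble::tibble(.rows = n_atoms)
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) != n_atoms) {
    stop("atom table must have one row per atom", call. = FALSE)
  }
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(n_atoms)
  if (!"name" %in% names(atoms)) atoms$name <- paste0("X", seq_len(n_atoms))
  if (!"element" %in% names(atoms)) {
    atoms$element <- toupper(substr(gsub("[0-9]", "", atoms$name), 1, 1))
  }
  if (!"resname" %in% names(atoms)) atoms$resname <- "UNK"
  if (!"resid" %in% names(atoms)) atoms$resid <- 1L
  if (!"molecule" %in% names(atoms)) atoms$molecule <- "other"
  atoms$index <- seq_len(n_atoms)
  structure(
    list(
      coords = coords, atoms = atoms,
      n_frames = dim(coords)[1], n_atoms = n_atoms
    ),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frame(s), %d atom(s) (%s)\n",
    x$n_frames, x$n_atoms,
    paste(
      sprintf("%s: %d", names(table(x$atoms$molecule)), table(x$atoms$molecule)),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Read a trajectory from PDB (and optionally DCD) files
#'
#' Uses \pkg{bio3d} to parse a PDB topology (multi-model PDB files provide
#' the frames directly) and, optionally, a DCD coordinate trajectory.
#' Molecules are classified from residue names: `ligand_resnames` mark the
#' ligand, recognised water residue names mark water, everything else is
#' receptor.
#'
#' @param pdb_file Path to a PDB file (topology; multi-model for frames).
#' @param traj_file Optional path to a DCD trajectory.
#' @param ligand_resnames Character vector of ligand residue names.
#' @param water_resnames Water residue names. Default HOH/WAT/TIP3/SOL.
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(pdb_file, traj_file = NULL,
                            ligand_resnames = character(),
                            water_resnames = c("HOH", "WAT", "TIP3", "SOL")) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB/DCD files requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(pdb_file, multi = TRUE)
  xyz <- pdb$xyz
  if (!is.null(traj_file)) {
    xyz <- bio3d::read.dcd(traj_file, verbose = FALSE)
  }
  xyz <- as.matrix(xyz)
  n_atoms <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nrow(xyz), n_atoms, 3))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3, length.out = n_atoms)]
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(!nzchar(element))) {
    element <- toupper(substr(gsub("[0-9]", "", at$elety), 1, 1))
  }
  molecule <- ifelse(
    at$resid %in% ligand_resnames, "ligand",
    ifelse(at$resid %in% water_resnames, "water", "receptor")
  )
  md_trajectory(
    coords,
    tibble::tibble(
      serial = at$eleno, name = at$elety, element = toupper(trimws(element)),
      resname = at$resid, resid = at$resno, molecule = molecule
    )
  )
}

#' Per-pair distance series over frames
#'
#' @param traj An [md_trajectory()].
#' @param pairs Data frame with integer columns `i` and `j` (atom indices),
#'   or a two-column matrix.
#' @return Numeric matrix `n_frames x n_pairs` of distances (Å).
#' @export
pair_distance_series <- function(traj, pairs) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.matrix(pairs)) pairs <- data.frame(i = pairs[, 1], j = pairs[, 2])
  d2 <- 0
  for (k in 1:3) {
    d2 <- d2 + (traj$coords[, pairs$i, k, drop = FALSE] -
      traj$coords[, pairs$j, k, drop = FALSE])^2
  }
  matrix(sqrt(d2), nrow = traj$n_frames)
}

# heavy atoms: everything that is not hydrogen
.heavy_idx <- function(traj) {
  which(!traj$atoms$element %in% c("H", "D"))
}
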