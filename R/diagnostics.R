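# Trajectory diagnostics: binding-site water occupancy, restrained-DoF time
# series, and per-atom RMSF.

#' Binding-site water occupancy
#'
#' Counts, per frame, the water molecules whose oxygen lies simultaneously
#' within `radius` of two chosen binding-site atoms (the overlap of two
#' spheres). Useful for tracking rehydration of a binding site during
#' decoupling.
#'
#' @param traj An [md_trajectory()].
#' @param center_atom_1,center_atom_2 Atom indices of the two sphere centres.
#' @param radius Sphere radius, Å. Default 8.
#' @param water_resnames Residue names recognised as water. Default
#'   HOH/WAT/TIP3/SOL.
#' @param water_atom Element symbol of the water atom used for the distance
#'   test. Default `"O"`.
#' @return A tibble of class `water_occupancy` with columns `frame`,
#'   `n_waters`; the mean over frames is stored in attribute
#'   `mean_occupancy`.
#' @export
water_occupancy <- function(traj, center_atom_1, center_atom_2, radius = 8,
                            water_resnames = c("HOH", "WAT", "TIP3", "SOL"),
                            water_atom = "O") {
  stopifnot(inherits(traj, "md_trajectory"))
  at <- traj$atoms
  if (!all(c(center_atom_1, center_atom_2) %in% at$index)) {
    stop("centre atoms not present in the topology", call. = FALSE)
  }
  wat <- which(at$resname %in% water_resnames & at$element == water_atom)
  d12 <- sqrt(sum((traj$coords[1, center_atom_1, ] -
    traj$coords[1, center_atom_2, ])^2))
  if (d12 > 2 * radius) {
    warning("sphere centres farther apart than 2 * radius: overlap is empty",
      call. = FALSE
    )
  }
  counts <- vapply(seq_len(traj$n_frames), function(f) {
    if (length(wat) == 0) return(0L)
    w <- traj$coords[f, wat, , drop = FALSE]
    d1 <- sqrt(
      (w[1, , 1] - traj$coords[f, center_atom_1, 1])^2 +
        (w[1, , 2] - traj$coords[f, center_atom_1, 2])^2 +
        (w[1, , 3] - traj$coords[f, center_atom_1, 3])^2
    )
    d2 <- sqrt(
      (w[1, , 1] - traj$coords[f, center_atom_2, 1])^2 +
        (w[1, , 2] - traj$coords[f, center_atom_2, 2])^2 +
        (w[1, , 3] - traj$coords[f, center_atom_2, 3])^2
    )
    sum(d1 <= radius & d2 <= radius)
  }, integer(1))
  out <- tibble::tibble(frame = seq_len(traj$n_frames), n_waters = counts)
  attr(out, "mean_occupancy") <- mean(counts)
  class(out) <- c("water_occupancy", class(out))
  out
}

#' Restrained degree-of-freedom time series
#'
#' Evaluates the restrained coordinates and the restraint energy on every
#' frame. For a Boresch restraint the columns are the six degrees of freedom
#' (distance in Å, angles and dihedrals in degrees) plus `energy`
#' (kcal mol⁻¹); for a distance restraint set, one distance column per pair
#' (`d1`, `d2`, ...) plus `energy`.
#'
#' @param traj An [md_trajectory()].
#' @param restraint A [boresch_restraint()] (with anchors set) or a
#'   [distance_restraint_set()].
#' @return A tibble of class `dof_timeseries`, one row per frame.
#' @export
dof_timeseries <- function(traj, restraint) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (inherits(restraint, "boresch_restraint")) {
    anchors <- restraint$anchors
    if (anyNA(anchors) || !all(anchors %in% traj$atoms$index)) {
      stop("restraint anchors missing from the topology", call. = FALSE)
    }
    dof <- .boresch_dof_frames(traj$coords, as.list(anchors))
    energy <- boresch_energy(restraint, dof)
    out <- tibble::tibble(
      frame = seq_len(traj$n_frames),
      r = dof$r,
      theta_A = dof$theta_A * 180 / pi,
      theta_B = dof$theta_B * 180 / pi,
      phi_A = dof$phi_A * 180 / pi,
      phi_B = dof$phi_B * 180 / pi,
      phi_C = dof$phi_C * 180 / pi,
      energy = energy
    )
  } else if (inherits(restraint, "distance_restraint_set")) {
    rr <- restraint$restraints
    if (!all(c(rr$receptor_atom, rr$ligand_atom) %in% traj$atoms$index)) {
      stop("restraint atoms missing from the topology", call. = FALSE)
    }
    d <- pair_distance_series(
      traj, data.frame(i = rr$receptor_atom, j = rr$ligand_atom)
    )
    energy <- distance_set_energy(restraint, d)
    colnames(d) <- paste0("d", seq_len(ncol(d)))
    out <- dplyr::bind_cols(
      tibble::tibble(frame = seq_len(traj$n_frames)),
      tibble::as_tibble(d),
      tibble::tibble(energy = energy)
    )
  } else {
    stop("unsupported restraint type", call. = FALSE)
  }
  class(out) <- c("dof_timeseries", class(out))
  out
}

# Kabsch optimal rotation Q (applied as x %*% Q) aligning x onto y
# (both n x 3, centred): Q = U diag(1, 1, d) V' for svd(x'y) = U D V',
# d = sign(det(U) det(V)) to exclude reflections.
.kabsch <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square fluctuation about the mean structure
#'
#' Per-atom RMSF of a selection after least-squares superposition of every
#' frame onto the mean structure of the selection (the superposition and the
#' mean are iterated to self-consistency, starting from an alignment onto
#' frame 1). An atom fluctuating isotropically with per-axis SD sigma has
#' RMSF ~ sigma * sqrt(3).
#'
#' @param traj An [md_trajectory()] with >= 2 frames.
#' @param selection Integer vector of atom indices. Default: all atoms.
#' @return A tibble with columns `atom` (index) and `rmsf` (Å).
#' @export
rmsf <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (traj$n_frames < 2) {
    stop("RMSF undefined for a single frame", call. = FALSE)
  }
  selection <- selection %||% seq_len(traj$n_atoms)
  frames <- lapply(seq_len(traj$n_frames), function(f) {
    m <- traj$coords[f, selection, , drop = FALSE]
    matrix(m, ncol = 3)
  })
  centre <- function(m) sweep(m, 2, colMeans(m))
  frames <- lapply(frames, centre)
  ref <- frames[[1]]
  for (iter in 1:3) {
    frames <- lapply(frames, function(m) m %*% .kabsch(m, ref))
    ref <- centre(Reduce(`+`, frames) / length(frames))
  }
  dev2 <- lapply(frames, function(m) rowSums((m - ref)^2))
  tibble::tibble(
    atom = selection,
    rmsf = sqrt(Reduce(`+`, dev2) / length(dev2))
  )
}
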