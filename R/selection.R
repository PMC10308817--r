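# Restraint selection from a trajectory of the fully interacting complex:
# low-variance atom pairs, Boresch candidate enumeration and ranking,
# force-constant fitting from observed variances, flat-bottom radius fitting.

#' Per-pair distance statistics from a trajectory
#'
#' Tracks all receptor-ligand heavy-atom pair distances over the trajectory
#' and keeps the pairs with the lowest standard deviation, the starting point
#' for all restraint selection. Eligible receptor atoms are the heavy atoms
#' within `contact_cutoff` of any ligand heavy atom in the *first* frame (the
#' cutoff is not re-evaluated per frame).
#'
#' @param traj An [md_trajectory()] with >= 2 frames.
#' @param receptor_atoms,ligand_atoms Optional integer vectors of candidate
#'   atom indices; default to heavy atoms of the respective molecules.
#' @param contact_cutoff First-frame receptor-ligand contact cutoff, Å.
#'   Default 10.
#' @param top_n Number of lowest-SD pairs to keep. Default 200.
#' @return A tibble of class `trajectory_stats` with columns `receptor_atom`,
#'   `ligand_atom`, `mean` (Å), `sd` (Å), sorted by ascending `sd` (ties
#'   broken by receptor then ligand index), at most `top_n` rows. The number
#'   of frames is stored in attribute `n_frames`.
#' @export
pair_distance_stats <- function(traj, receptor_atoms = NULL,
                                ligand_atoms = NULL,
                                contact_cutoff = 10, top_n = 200) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (traj$n_frames < 2) {
    stop("variance undefined: need at least 2 frames", call. = FALSE)
  }
  heavy <- .heavy_idx(traj)
  if (is.null(ligand_atoms)) {
    ligand_atoms <- intersect(which(traj$atoms$molecule == "ligand"), heavy)
  }
  if (is.null(receptor_atoms)) {
    receptor_atoms <- intersect(
      which(traj$atoms$molecule == "receptor"), heavy
    )
  }
  if (length(ligand_atoms) == 0 || length(receptor_atoms) == 0) {
    stop("no eligible receptor or ligand atoms", call. = FALSE)
  }
  # first-frame contact filter on the receptor side
  f1 <- traj$coords[1, , , drop = TRUE]
  keep <- vapply(receptor_atoms, function(i) {
    min(.row_norm(
      f1[ligand_atoms, , drop = FALSE] -
        matrix(f1[i, ], length(ligand_atoms), 3, byrow = TRUE)
    )) <= contact_cutoff
  }, logical(1))
  receptor_atoms <- receptor_atoms[keep]
  if (length(receptor_atoms) == 0) {
    stop("no receptor heavy atoms within the contact cutoff in frame 1",
      call. = FALSE
    )
  }
  pairs <- expand.grid(
    receptor_atom = receptor_atoms, ligand_atom = ligand_atoms
  )
  d <- pair_distance_series(
    traj, data.frame(i = pairs$receptor_atom, j = pairs$ligand_atom)
  )
  out <- tibble::tibble(
    receptor_atom = pairs$receptor_atom,
    ligand_atom = pairs$ligand_atom,
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd)
  )
  out <- dplyr::arrange(out, .data$sd, .data$receptor_atom, .data$ligand_atom)
  out <- utils::head(out, top_n)
  attr(out, "n_frames") <- traj$n_frames
  attr(out, "params") <- list(contact_cutoff = contact_cutoff, top_n = top_n)
  class(out) <- c("trajectory_stats", class(out))
  out
}

#' Select multiple distance restraints by the unique-anchor rule
#'
#' Scans the ranked pair table in order of increasing distance SD and keeps a
#' pair only if neither of its atoms has already been used by a kept pair, so
#' every atom anchors at most one restraint. Equilibrium distances are the
#' trajectory means; force constants are left unset (`NA`) pending fitting.
#'
#' @param stats A [pair_distance_stats()] table.
#' @param label Label for the returned set.
#' @return A [distance_restraint_set()] with `K = NA` and `r_fb = 0`.
#' @export
select_distance_restraints <- function(stats, label = "minimum-variance") {
  stopifnot(nrow(stats) > 0)
  used <- integer(0)
  keep <- logical(nrow(stats))
  for (k in seq_len(nrow(stats))) {
    p <- c(stats$receptor_atom[k], stats$ligand_atom[k])
    if (!any(p %in% used)) {
      keep[k] <- TRUE
      used <- c(used, p)
    }
  }
  kept <- stats[keep, ]
  distance_restraint_set(
    tibble::tibble(
      receptor_atom = kept$receptor_atom, ligand_atom = kept$ligand_atom,
      r0 = kept$mean, r_fb = 0, K = NA_real_
    ),
    label = label
  )
}

#' Infer a bonded heavy-atom graph from first-frame distances
#'
#' Two heavy atoms of the same molecule are taken as bonded when closer than
#' `cutoff` in the first frame. Sufficient for anchor-completion enumeration;
#' supply an explicit bond table when a real topology is available.
#'
#' @param traj An [md_trajectory()].
#' @param cutoff Covalent distance cutoff, Å. Default 1.9.
#' @return Tibble with integer columns `i`, `j` (i < j).
#' @export
infer_bonds <- function(traj, cutoff = 1.9) {
  heavy <- .heavy_idx(traj)
  f1 <- traj$coords[1, heavy, , drop = TRUE]
  n <- length(heavy)
  pr <- utils::combn(n, 2)
  d <- .row_norm(f1[pr[1, ], , drop = FALSE] - f1[pr[2, ], , drop = FALSE])
  same_mol <- traj$atoms$molecule[heavy[pr[1, ]]] ==
    traj$atoms$molecule[heavy[pr[2, ]]]
  sel <- d <= cutoff & same_mol
  tibble::tibble(i = heavy[pr[1, sel]], j = heavy[pr[2, sel]])
}

.neighbour_list <- function(bonds, n_atoms) {
  nb <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# circular mean / variance for dihedral series (variance of deviations
# wrapped into (-pi, pi] about the circular mean, n-1 denominator)
circular_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

circular_var <- function(x) {
  dev <- wrap_angle(x - circular_mean(x))
  sum(dev^2) / (length(dev) - 1)
}

#' Enumerate and rank Boresch anchor candidates
#'
#' Every pair in the low-variance table is taken as candidate anchors (a, A).
#' Each pair is completed with all bonded heavy-atom choices: b bonded to a,
#' c bonded to b (c != a), and mirrored on the ligand side (B bonded to A,
#' C bonded to B, C != A). For every completion the six Boresch degrees of
#' freedom are evaluated on every frame; candidates whose mean theta_A or
#' theta_B falls below `angle_min_deg` or above `angle_max_deg` are
#' discarded, and the rest are ranked by ascending total variance (the sum
#' of the six per-DoF variances; Å² and rad² are added directly).
#' Dihedral statistics are circular: the mean is the arctangent of the mean
#' sine and cosine, and variances are computed from deviations wrapped into
#' (-pi, pi] about that mean.
#'
#' @param stats A [pair_distance_stats()] table (`receptor_atom` = a,
#'   `ligand_atom` = A candidates).
#' @param traj The trajectory the stats came from.
#' @param bonds Bond table (`i`, `j`); defaults to [infer_bonds()].
#' @param angle_min_deg,angle_max_deg Mean-angle filter bounds in degrees.
#'   Defaults 30 and 150.
#' @param score `"direct"` (default) sums the six variances; `"weighted"`
#'   divides each variance by the variance a thermal harmonic restraint of
#'   reference stiffness `reference_k` would have (`kT / reference_k`).
#' @param reference_k Reference stiffness for the weighted score
#'   (kcal mol⁻¹ Å⁻² for r, kcal mol⁻¹ rad⁻² for angles). Default 10.
#' @param context A [thermo_context()] (used by the weighted score).
#' @return A tibble of class `boresch_candidates`: anchor columns `a`, `b`,
#'   `c`, `A`, `B`, `C`, per-DoF means (`mean_r`, ..., radians for angles)
#'   and variances (`var_r` in Å², others in rad²), and `score`, sorted
#'   ascending by score.
#' @export
enumerate_boresch_candidates <- function(stats, traj, bonds = NULL,
                                         angle_min_deg = 30,
                                         angle_max_deg = 150,
                                         score = c("direct", "weighted"),
                                         reference_k = 10,
                                         context = thermo_context()) {
  score <- match.arg(score)
  stopifnot(inherits(traj, "md_trajectory"), nrow(stats) > 0)
  if (is.null(bonds)) bonds <- infer_bonds(traj)
  nb <- .neighbour_list(bonds, traj$n_atoms)
  cands <- list()
  for (k in seq_len(nrow(stats))) {
    a <- stats$receptor_atom[k]
    A <- stats$ligand_atom[k]
    if (length(nb[[a]]) == 0 || length(nb[[A]]) == 0) {
      message(sprintf(
        "skipping pair (%d, %d): anchor atom without heavy neighbours", a, A
      ))
      next
    }
    for (b in nb[[a]]) {
      cs <- setdiff(nb[[b]], a)
      if (length(cs) == 0) next
      for (B in nb[[A]]) {
        Cs <- setdiff(nb[[B]], A)
        if (length(Cs) == 0) next
        grid <- expand.grid(cc = cs, CC = Cs)
        for (g in seq_len(nrow(grid))) {
          cands[[length(cands) + 1]] <-
            c(a = a, b = b, c = grid$cc[g], A = A, B = B, C = grid$CC[g])
        }
      }
    }
  }
  if (length(cands) == 0) stop("no Boresch candidates found", call. = FALSE)
  cand <- dplyr::distinct(tibble::as_tibble(do.call(rbind, cands)))

  stats_one <- function(anchors) {
    dof <- .boresch_dof_frames(traj$coords, as.list(anchors))
    means <- c(
      mean(dof$r), mean(dof$theta_A), mean(dof$theta_B),
      circular_mean(dof$phi_A), circular_mean(dof$phi_B),
      circular_mean(dof$phi_C)
    )
    vars <- c(
      stats::var(dof$r), stats::var(dof$theta_A), stats::var(dof$theta_B),
      circular_var(dof$phi_A), circular_var(dof$phi_B),
      circular_var(dof$phi_C)
    )
    c(means, vars)
  }
  m <- t(apply(as.matrix(cand), 1, stats_one))
  colnames(m) <- c(
    paste0("mean_", .boresch_dof_names), paste0("var_", .boresch_dof_names)
  )
  out <- dplyr::bind_cols(cand, tibble::as_tibble(m))
  lo <- angle_min_deg * pi / 180
  hi <- angle_max_deg * pi / 180
  out <- dplyr::filter(
    out,
    .data$mean_theta_A >= lo, .data$mean_theta_A <= hi,
    .data$mean_theta_B >= lo, .data$mean_theta_B <= hi
  )
  if (nrow(out) == 0) {
    stop("all candidates rejected by the angle filter", call. = FALSE)
  }
  vars <- as.matrix(out[, paste0("var_", .boresch_dof_names)])
  out$score <- if (score == "direct") {
    rowSums(vars)
  } else {
    rowSums(vars / (context$kT / reference_k))
  }
  out <- dplyr::arrange(out, .data$score)
  class(out) <- c("boresch_candidates", class(out))
  out
}

#' Minimum collinearity energy penalty of a Boresch restraint
#'
#' The lowest harmonic energy cost of driving theta_A or theta_B to 0 or pi,
#' i.e. `min over targets of K/2 (theta_target - theta_0)^2`. Restraints with
#' a small penalty are prone to collinearity instabilities during sampling;
#' a common screen flags candidates below about 10 kT, though crashes have
#' been observed even near that level, so the threshold is a floor rather
#' than a guarantee.
#'
#' @param k_theta_A,k_theta_B Angular force constants, kcal mol⁻¹ rad⁻²
#'   (vectorised).
#' @param theta_A0,theta_B0 Equilibrium angles, radians.
#' @return Minimum penalty, kcal mol⁻¹ (0 whenever either K is 0).
#' @seealso [boresch_from_candidate()] which applies the screen.
#' @export
collinearity_penalty <- function(k_theta_A, theta_A0, k_theta_B, theta_B0) {
  pmin(
    0.5 * k_theta_A * theta_A0^2,
    0.5 * k_theta_A * (pi - theta_A0)^2,
    0.5 * k_theta_B * theta_B0^2,
    0.5 * k_theta_B * (pi - theta_B0)^2
  )
}

#' Fit force constants from observed variances
#'
#' In the decoupled state a harmonic restraint `K/2 (x - x0)^2` samples a
#' Gaussian with variance `kT / K`. Choosing `K = kT / var(x)` therefore
#' makes the restrained distribution match the (assumed Gaussian)
#' distribution observed in the coupled state.
#'
#' @param variances Named numeric vector of per-DoF variances (Å² for
#'   distances, rad² for angles), all > 0.
#' @param context A [thermo_context()].
#' @return Named numeric vector of force constants (kcal mol⁻¹ Å⁻² or
#'   kcal mol⁻¹ rad⁻²).
#' @export
fit_force_constants <- function(variances, context = thermo_context()) {
  context <- as_thermo_context(context)
  if (any(variances <= 0)) {
    stop(paste(
      "zero variance would give an infinite force constant;",
      "cap the variance or set the force constant by hand"
    ), call. = FALSE)
  }
  context$kT / variances
}

#' Build a fitted Boresch restraint from a ranked candidate
#'
#' Takes one row of [enumerate_boresch_candidates()] output, sets equilibria
#' to the trajectory means and force constants to `kT / variance`
#' ([fit_force_constants()]), and screens the result for collinearity risk.
#'
#' @param candidates A `boresch_candidates` table.
#' @param which Row to use (default 1, the best-scoring candidate).
#' @param context A [thermo_context()].
#' @param collinearity_threshold_kT Flagging threshold in units of kT.
#'   Default 10. A warning is raised when the minimum collinearity penalty
#'   falls below it.
#' @return A [boresch_restraint()] with attributes `collinearity_penalty`
#'   (kcal mol⁻¹) and `collinearity_flagged`.
#' @export
boresch_from_candidate <- function(candidates, which = 1,
                                   context = thermo_context(),
                                   collinearity_threshold_kT = 10) {
  context <- as_thermo_context(context)
  row <- candidates[which, ]
  vars <- unlist(row[paste0("var_", .boresch_dof_names)])
  names(vars) <- .boresch_dof_names
  k <- fit_force_constants(vars, context)
  br <- boresch_restraint(
    anchors = unlist(row[c("a", "b", "c", "A", "B", "C")]),
    r0 = row$mean_r, theta_A0 = row$mean_theta_A, theta_B0 = row$mean_theta_B,
    phi_A0 = row$mean_phi_A, phi_B0 = row$mean_phi_B, phi_C0 = row$mean_phi_C,
    k_r = k[["r"]], k_theta_A = k[["theta_A"]], k_theta_B = k[["theta_B"]],
    k_phi_A = k[["phi_A"]], k_phi_B = k[["phi_B"]], k_phi_C = k[["phi_C"]]
  )
  pen <- collinearity_penalty(
    k[["theta_A"]], row$mean_theta_A, k[["theta_B"]], row$mean_theta_B
  )
  flagged <- pen < collinearity_threshold_kT * context$kT
  if (flagged) {
    warning(sprintf(
      "collinearity penalty %.2f kcal/mol is below %g kT: restraint may be unstable",
      pen, collinearity_threshold_kT
    ), call. = FALSE)
  }
  attr(br, "collinearity_penalty") <- pen
  attr(br, "collinearity_flagged") <- flagged
  br
}

#' Fit flat-bottom radii to a distance series
#'
#' Sets each restraint's equilibrium distance to the series mean and its
#' flat-bottom radius either to the maximum excursion from the mean (so the
#' restraint energy is exactly zero on every fitting frame - "as small as
#' possible without engaging") or to a percentile of the excursions.
#'
#' @param set A [distance_restraint_set()].
#' @param traj Trajectory used for fitting.
#' @param mode `"max_excursion"` (default) or `"percentile"`.
#' @param percentile Percentile of `|r - r0|` used when
#'   `mode = "percentile"`. Default 100 (equals max_excursion).
#' @return The set with updated `r0` and `r_fb`.
#' @export
fit_flat_bottom_radii <- function(set, traj,
                                  mode = c("max_excursion", "percentile"),
                                  percentile = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "distance_restraint_set"))
  d <- pair_distance_series(
    traj,
    data.frame(i = set$restraints$receptor_atom,
               j = set$restraints$ligand_atom)
  )
  r0 <- colMeans(d)
  exc <- abs(d - matrix(r0, nrow(d), ncol(d), byrow = TRUE))
  r_fb <- if (mode == "max_excursion") {
    apply(exc, 2, max)
  } else {
    apply(exc, 2, stats::quantile, probs = percentile / 100, names = FALSE)
  }
  set$restraints$r0 <- r0
  set$restraints$r_fb <- r_fb
  set
}
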