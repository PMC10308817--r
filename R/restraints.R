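#' Boresch restraint
#'
#' A Boresch restraint ties the six relative external degrees of freedom of a
#' ligand to a receptor through six anchor atoms: three in the receptor
#' (a, b, c) and three in the ligand (A, B, C). The restrained coordinates are
#' the distance r = |a-A|, the bond angles theta_A (b-a-A) and theta_B
#' (a-A-B), and the dihedrals phi_A (c-b-a-A), phi_B (b-a-A-B) and phi_C
#' (a-A-B-C). Each is restrained harmonically, `u(x) = K/2 (x - x0)^2`, with
#' dihedral deviations wrapped into (-pi, pi]. A force constant of zero marks
#' a degree of freedom as unrestrained; in particular setting `k_theta_B`,
#' `k_phi_B` and `k_phi_C` to zero restrains only the position of anchor A
#' (no orientational restraint).
#'
#' @param anchors Named list or vector of the six anchor atom indices, names
#'   `a`, `b`, `c`, `A`, `B`, `C`. Indices are 1-based and refer to rows of
#'   the trajectory atom table (PDB serials are carried alongside in files).
#'   May be `NA` for purely parametric restraints.
#' @param r0 Equilibrium distance, Å (> 0).
#' @param theta_A0,theta_B0 Equilibrium bond angles, radians, strictly in
#'   (0, pi).
#' @param phi_A0,phi_B0,phi_C0 Equilibrium dihedrals, radians in (-pi, pi].
#' @param k_r Force constant for r, kcal mol⁻¹ Å⁻² (>= 0).
#' @param k_theta_A,k_theta_B,k_phi_A,k_phi_B,k_phi_C Angular force
#'   constants, kcal mol⁻¹ rad⁻² (>= 0; 0 = unrestrained).
#'
#' @return An object of class `boresch_restraint`.
#' @examples
#' br <- boresch_restraint(
#'   r0 = 5, theta_A0 = pi / 2, theta_B0 = pi / 2,
#'   phi_A0 = 0, phi_B0 = 0, phi_C0 = 0,
#'   k_r = 10, k_theta_A = 10, k_theta_B = 10,
#'   k_phi_A = 10, k_phi_B = 10, k_phi_C = 10
#' )
#' @export
boresch_restraint <- function(anchors = NULL,
                              r0, theta_A0, theta_B0,
                              phi_A0, phi_B0, phi_C0,
                              k_r, k_theta_A, k_theta_B,
                              k_phi_A, k_phi_B, k_phi_C) {
  if (is.null(anchors)) {
    anchors <- stats::setNames(rep(NA_integer_, 6), .boresch_anchor_names)
  }
  anchors <- unlist(anchors)
  if (!setequal(names(anchors), .boresch_anchor_names)) {
    stop("anchors must be named a, b, c, A, B, C", call. = FALSE)
  }
  anchors <- anchors[.boresch_anchor_names]
  eq <- c(
    r = r0, theta_A = theta_A0, theta_B = theta_B0,
    phi_A = phi_A0, phi_B = phi_B0, phi_C = phi_C0
  )
  k <- c(
    r = k_r, theta_A = k_theta_A, theta_B = k_theta_B,
    phi_A = k_phi_A, phi_B = k_phi_B, phi_C = k_phi_C
  )
  if (!is.finite(r0) || r0 <= 0) stop("r0 must be > 0", call. = FALSE)
  if (theta_A0 <= 0 || theta_A0 >= pi || theta_B0 <= 0 || theta_B0 >= pi) {
    stop("theta equilibria must lie strictly in (0, pi) radians", call. = FALSE)
  }
  phis <- eq[c("phi_A", "phi_B", "phi_C")]
  if (any(phis <= -pi - 1e-12 | phis > pi + 1e-12)) {
    stop("dihedral equilibria must lie in (-pi, pi] radians", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("force constants must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(anchors = anchors, equilibrium = eq, force_constants = k),
    class = "boresch_restraint"
  )
}

.boresch_anchor_names <- c("a", "b", "c", "A", "B", "C")
.boresch_dof_names <- c("r", "theta_A", "theta_B", "phi_A", "phi_B", "phi_C")

#' @export
print.boresch_restraint <- function(x, ...) {
  cat("<boresch_restraint>\n")
  eq <- x$equilibrium
  shown <- c(eq["r"], eq[-1] * 180 / pi)
  cat(sprintf(
    "  %-8s eq %8.3f %-4s K %8.3f %s\n",
    .boresch_dof_names, shown,
    c("Å", rep("deg", 5)),
    x$force_constants,
    c("kcal/mol/Å²", rep("kcal/mol/rad²", 5))
  ), sep = "")
  invisible(x)
}

#' Distance restraint set
#'
#' A set of N >= 1 intermolecular distance restraints, each between one
#' receptor atom and one ligand atom, with energy per pair
#' `K/2 (r - r0)^2` when the flat-bottom radius `r_fb` is zero, and
#' `0` inside `|r - r0| <= r_fb`, `K/2 (|r - r0| - r_fb)^2` outside,
#' otherwise. The total restraint energy is the sum over pairs.
#'
#' @param restraints Data frame with columns `receptor_atom`, `ligand_atom`,
#'   `r0` (Å, >= 0), `r_fb` (Å, >= 0; 0 = pure harmonic) and `K`
#'   (kcal mol⁻¹ Å⁻², >= 0; `Inf` = hard wall at `r0 + r_fb`). `K` may be
#'   `NA` for sets awaiting force-constant fitting.
#' @param label Optional text label for the set.
#' @return An object of class `distance_restraint_set`; the `$restraints`
#'   field is a tibble.
#' @examples
#' dset <- distance_restraint_set(
#'   data.frame(receptor_atom = 1, ligand_atom = 2, r0 = 3, r_fb = 0, K = 40)
#' )
#' @export
distance_restraint_set <- function(restraints, label = "") {
  restraints <- tibble::as_tibble(restraints)
  needed <- c("receptor_atom", "ligand_atom", "r0", "K")
  if (!all(needed %in% names(restraints))) {
    stop("restraints need columns receptor_atom, ligand_atom, r0, K",
      call. = FALSE
    )
  }
  if (!"r_fb" %in% names(restraints)) restraints$r_fb <- 0
  if (nrow(restraints) < 1) stop("need at least one restraint", call. = FALSE)
  if (any(restraints$r0 < 0) || any(restraints$r_fb < 0)) {
    stop("r0 and r_fb must be >= 0", call. = FALSE)
  }
  if (any(!is.na(restraints$K) & restraints$K < 0)) {
    stop("force constants must be >= 0", call. = FALSE)
  }
  key <- paste(restraints$receptor_atom, restraints$ligand_atom)
  if (anyDuplicated(key)) stop("duplicate atom pairs in set", call. = FALSE)
  structure(
    list(
      restraints = restraints[, c(
        "receptor_atom", "ligand_atom", "r0", "r_fb", "K"
      )],
      label = label
    ),
    class = "distance_restraint_set"
  )
}

#' @export
print.distance_restraint_set <- function(x, ...) {
  cat(sprintf(
    "<distance_restraint_set> %d restraint(s)%s\n", nrow(x$restraints),
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  ))
  print(x$restraints, n = 10)
  invisible(x)
}

#' Intramolecular rigidification restraint set
#'
#' Harmonic distance restraints between all pairs of anchor atoms within one
#' molecule, used to rigidify the anchor geometry so that a rigid-body
#' release correction becomes exact. Equilibrium distances are taken from the
#' supplied (typically trajectory-average) coordinates.
#'
#' @param coords Matrix (n x 3) of anchor coordinates, Å.
#' @param atoms Integer vector of atom indices (length n, all in the same
#'   molecule). Defaults to `seq_len(nrow(coords))`.
#' @param K Force constant for every pair, kcal mol⁻¹ Å⁻². Default 75.
#' @return A `distance_restraint_set` covering all `choose(n, 2)` pairs
#'   (both members of each pair lie in the same molecule; the
#'   `receptor_atom`/`ligand_atom` columns hold the first/second pair atom).
#' @export
intramolecular_restraint_set <- function(coords, atoms = seq_len(nrow(coords)),
                                         K = 75) {
  coords <- .as_mat3(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least two anchor atoms", call. = FALSE)
  pairs <- utils::combn(n, 2)
  d <- .row_norm(
    coords[pairs[1, ], , drop = FALSE] - coords[pairs[2, ], , drop = FALSE]
  )
  distance_restraint_set(
    tibble::tibble(
      receptor_atom = atoms[pairs[1, ]],
      ligand_atom = atoms[pairs[2, ]],
      r0 = d, r_fb = 0, K = K
    ),
    label = "intramolecular"
  )
}

#' Boresch degrees of freedom from anchor coordinates
#'
#' Computes (r, theta_A, theta_B, phi_A, phi_B, phi_C) from the Cartesian
#' coordinates of the six anchor atoms. Dihedrals follow the atan2 two-normal
#' formulation, positive for a right-handed rotation viewed along the central
#' bond; values are invariant under rigid rotation and translation of all six
#' anchors.
#'
#' @param coords 6 x 3 numeric matrix of anchor coordinates in the order
#'   a, b, c, A, B, C (Å).
#' @return Named numeric vector `r` (Å), `theta_A`, `theta_B`, `phi_A`,
#'   `phi_B`, `phi_C` (radians; angles in `[0, pi]`, dihedrals in
#'   `(-pi, pi]`). If any contiguous anchor triple is collinear the affected
#'   dihedral is still reported but a collinearity warning is raised.
#' @examples
#' xyz <- rbind(
#'   a = c(0, 0, 0), b = c(0, 1, 0), c = c(-1, 1, 0),
#'   A = c(1, 0, 0), B = c(2, -1, 0), C = c(3, -1, 0)
#' )
#' boresch_dof(xyz[c("a", "b", "c", "A", "B", "C"), ])
#' @export
boresch_dof <- function(coords) {
  coords <- .as_mat3(coords)
  if (nrow(coords) != 6) stop("coords must be 6 x 3 (a, b, c, A, B, C)",
    call. = FALSE
  )
  consecutive <- list(c(3, 2), c(2, 1), c(1, 4), c(4, 5), c(5, 6)) # c-b-a-A-B-C
  for (p in consecutive) {
    if (sum((coords[p[1], ] - coords[p[2], ])^2) < 1e-20) {
      stop("degenerate geometry: coincident consecutive anchor atoms",
        call. = FALSE
      )
    }
  }
  out <- .boresch_dof_mat(
    a = coords[1, , drop = FALSE], b = coords[2, , drop = FALSE],
    c = coords[3, , drop = FALSE],
    A = coords[4, , drop = FALSE], B = coords[5, , drop = FALSE],
    C = coords[6, , drop = FALSE]
  )
  dof <- vapply(out, function(v) v[[1]], numeric(1))
  # a collinear triple leaves the dihedral(s) sharing its central bond
  # ill-defined
  tol <- 1e-8
  col_A <- min(dof["theta_A"], pi - dof["theta_A"]) < tol
  col_B <- min(dof["theta_B"], pi - dof["theta_B"]) < tol
  bc <- .row_angle(coords[3, ], coords[2, ], coords[1, ]) # c-b-a
  BC <- .row_angle(coords[4, ], coords[5, ], coords[6, ]) # A-B-C
  col_bc <- min(bc, pi - bc) < tol
  col_BC <- min(BC, pi - BC) < tol
  if (col_A || col_B || col_bc || col_BC) {
    bad <- unique(c(
      if (col_A || col_bc) "phi_A", if (col_A || col_B) "phi_B",
      if (col_B || col_BC) "phi_C"
    ))
    warning(
      sprintf(
        "collinear anchor triple: dihedral(s) %s undefined",
        paste(bad, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  dof
}

# Vectorised over rows of A, B, C with fixed (or equally vectorised) a, b, c.
.boresch_dof_mat <- function(a, b, c, A, B, C) {
  list(
    r = .row_norm(.as_mat3(A) - .as_mat3(a, nrow(.as_mat3(A)))),
    theta_A = .row_angle(b, a, A),
    theta_B = .row_angle(a, A, B),
    phi_A = .row_dihedral(c, b, a, A),
    phi_B = .row_dihedral(b, a, A, B),
    phi_C = .row_dihedral(a, A, B, C)
  )
}

# DoF series across trajectory frames for anchor indices (a,b,c,A,B,C).
.boresch_dof_frames <- function(coords, anchors) {
  g <- function(i) coords[, anchors[[i]], , drop = TRUE]
  .boresch_dof_mat(
    a = g("a"), b = g("b"), c = g("c"), A = g("A"), B = g("B"), C = g("C")
  )
}

#' Boresch restraint energy
#'
#' Harmonic restraint energy `sum_x K_x/2 (x - x0)^2` over the six degrees of
#' freedom, with dihedral deviations wrapped into (-pi, pi] before squaring.
#' Degrees of freedom with `K = 0` contribute nothing.
#'
#' @param restraint A [boresch_restraint()].
#' @param dof Named numeric vector as returned by [boresch_dof()], or a list
#'   of equal-length vectors for vectorised evaluation.
#' @return Energy in kcal mol⁻¹ (vector if `dof` holds vectors); >= 0, zero
#'   iff every restrained degree of freedom is at its equilibrium.
#' @export
boresch_energy <- function(restraint, dof) {
  stopifnot(inherits(restraint, "boresch_restraint"))
  k <- restraint$force_constants
  eq <- restraint$equilibrium
  dev_r <- dof[["r"]] - eq[["r"]]
  dev_tA <- dof[["theta_A"]] - eq[["theta_A"]]
  dev_tB <- dof[["theta_B"]] - eq[["theta_B"]]
  dev_pA <- wrap_angle(dof[["phi_A"]] - eq[["phi_A"]])
  dev_pB <- wrap_angle(dof[["phi_B"]] - eq[["phi_B"]])
  dev_pC <- wrap_angle(dof[["phi_C"]] - eq[["phi_C"]])
  0.5 * (
    k[["r"]] * dev_r^2 +
      k[["theta_A"]] * dev_tA^2 + k[["theta_B"]] * dev_tB^2 +
      k[["phi_A"]] * dev_pA^2 + k[["phi_B"]] * dev_pB^2 +
      k[["phi_C"]] * dev_pC^2
  )
}

#' Total energy of a distance restraint set
#'
#' @param set A [distance_restraint_set()].
#' @param distances Numeric vector of distances (Å), one per restraint, in
#'   set order; or a matrix with one column per restraint for vectorised
#'   evaluation over rows.
#' @return Total restraint energy, kcal mol⁻¹ (vector for matrix input).
#' @export
distance_set_energy <- function(set, distances) {
  stopifnot(inherits(set, "distance_restraint_set"))
  r <- set$restraints
  if (is.matrix(distances)) {
    if (ncol(distances) != nrow(r)) {
      stop("distance count mismatch: need one column per restraint",
        call. = FALSE
      )
    }
    e <- 0
    for (i in seq_len(nrow(r))) {
      e <- e + .pair_energy(distances[, i], r$r0[i], r$r_fb[i], r$K[i])
    }
    return(e)
  }
  if (length(distances) != nrow(r)) {
    stop("distance count mismatch: need one distance per restraint",
      call. = FALSE
    )
  }
  if (any(distances < 0)) stop("distances must be >= 0", call. = FALSE)
  sum(.pair_energy(distances, r$r0, r$r_fb, r$K))
}

.pair_energy <- function(r, r0, r_fb, K) {
  excess <- pmax(abs(r - r0) - r_fb, 0)
  out <- 0.5 * K * excess^2
  if (any(inf <- is.infinite(K))) { # hard wall: 0 inside, Inf outside
    out[inf & excess == 0] <- 0
  }
  out
}

#' Scale restraint force constants with a coupling parameter
#'
#' Multiplies every force constant by `lambda^power`, leaving equilibrium
#' values untouched. `lambda = 0` turns all restraints off and `lambda = 1`
#' is the identity. Restraint introduction/removal schedules conventionally
#' use `power = 1` (linear) or `power = 5`.
#'
#' @param x A [boresch_restraint()] or [distance_restraint_set()].
#' @param lambda Coupling parameter in `[0, 1]`.
#' @param power Scaling exponent, 1 or 5.
#' @return An object of the same class with scaled force constants.
#' @export
scale_restraints <- function(x, lambda, power = 5) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  if (!power %in% c(1, 5)) stop("power must be 1 or 5", call. = FALSE)
  UseMethod("scale_restraints")
}

#' @export
scale_restraints.boresch_restraint <- function(x, lambda, power = 5) {
  x$force_constants <- x$force_constants * lambda^power
  x
}

#' @export
scale_restraints.distance_restraint_set <- function(x, lambda, power = 5) {
  x$restraints$K <- x$restraints$K * lambda^power
  x
}

#' Coupling-parameter schedules
#'
#' Builds and validates an ordered schedule of lambda windows in `[0, 1]`
#' with both endpoints present. Named presets reproduce published window
#' lists for each alchemical stage: `"free_discharge_8"` and
#' `"bound_discharge_8"` (8 evenly spaced), `"free_vanish_18"` (18 unevenly
#' spaced), `"bound_restrain_6"` (6 unevenly spaced), `"bound_vanish_36"`
#' (31 evenly spaced to 0.75 then 5 to 1.0) and `"restraint_release_21"`
#' (21 evenly spaced, used with `power = 5` scaling).
#'
#' @param kind `"evenly_spaced"`, `"explicit"`, or `"preset"`.
#' @param n Number of windows for `evenly_spaced` (>= 2).
#' @param values Numeric vector for `explicit`.
#' @param preset Preset name for `preset`.
#' @return Numeric vector of validated lambda values.
#' @examples
#' lambda_schedule("evenly_spaced", n = 21)
#' lambda_schedule("preset", preset = "free_vanish_18")
#' @export
lambda_schedule <- function(kind = c("evenly_spaced", "explicit", "preset"),
                            n = NULL, values = NULL, preset = NULL) {
  kind <- match.arg(kind)
  values <- switch(kind,
    evenly_spaced = {
      if (is.null(n) || n < 2) stop("need n >= 2", call. = FALSE)
      seq(0, 1, length.out = n)
    },
    explicit = values,
    preset = {
      if (is.null(preset) || !preset %in% names(.lambda_presets)) {
        stop(
          sprintf(
            "unknown preset; available: %s",
            paste(names(.lambda_presets), collapse = ", ")
          ),
          call. = FALSE
        )
      }
      .lambda_presets[[preset]]
    }
  )
  if (is.null(values) || length(values) < 2) {
    stop("schedule needs at least two values", call. = FALSE)
  }
  if (any(values < 0 | values > 1)) {
    stop("lambda values must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("lambda values must be strictly increasing", call. = FALSE)
  }
  if (abs(values[1]) > 1e-12 || abs(values[length(values)] - 1) > 1e-12) {
    stop("schedule must start at 0 and end at 1", call. = FALSE)
  }
  values
}

.lambda_presets <- list(
  free_discharge_8 = seq(0, 1, length.out = 8),
  free_vanish_18 = c(
    0.000, 0.028, 0.056, 0.111, 0.167, 0.222, 0.278, 0.333, 0.389, 0.444,
    0.500, 0.556, 0.611, 0.667, 0.722, 0.778, 0.889, 1.000
  ),
  bound_restrain_6 = c(0.000, 0.125, 0.250, 0.375, 0.500, 1.000),
  bound_discharge_8 = seq(0, 1, length.out = 8),
  bound_vanish_36 = c(
    seq(0, 0.750, length.out = 31), seq(0.750, 1, length.out = 6)[-1]
  ),
  restraint_release_21 = seq(0, 1, length.out = 21)
)
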