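# Monte Carlo estimator of restraint-confinement free energies: an
# independent stochastic check on the deterministic release routes.

# Apply the z-y'-z'' Euler rotation (vectorised over samples) to one fixed
# vector v; returns an n x 3 matrix.
.euler_apply <- function(phi, theta, psi, v) {
  cf <- cos(phi); sf <- sin(phi)
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(psi); sp <- sin(psi)
  cbind(
    v[1] * (cf * ct * cp - sf * sp) + v[2] * (-cf * ct * sp - sf * cp) +
      v[3] * cf * st,
    v[1] * (sf * ct * cp + cf * sp) + v[2] * (-sf * ct * sp + cf * cp) +
      v[3] * sf * st,
    v[1] * (-st * cp) + v[2] * (st * sp) + v[3] * ct
  )
}

# Haar-uniform Euler angles: psi, phi uniform on [0, 2pi), cos(theta)
# uniform on [-1, 1].
.sample_euler <- function(n) {
  list(
    phi = stats::runif(n, 0, 2 * pi),
    theta = acos(stats::runif(n, -1, 1)),
    psi = stats::runif(n, 0, 2 * pi)
  )
}

#' Reference rigid geometry for a Boresch restraint
#'
#' Builds an arbitrary non-collinear rigid anchor geometry (receptor a, b, c
#' and ligand A, B, C) on which a Boresch restraint's energy depends only on
#' the six relative external degrees of freedom. Because the configurational
#' integral over rigid-body poses is independent of the internal anchor
#' geometry, any such geometry reproduces the Boresch release free energy
#' under rigid-body integration - the basis of the grid and Monte Carlo
#' cross-checks.
#'
#' @param restraint A [boresch_restraint()] (only used for labelling; the
#'   geometry itself is generic).
#' @return A [rigid_anchor_geometry()] with receptor rows a, b, c and ligand
#'   rows A, B, C.
#' @export
boresch_reference_geometry <- function(restraint) {
  stopifnot(inherits(restraint, "boresch_restraint"))
  rigid_anchor_geometry(
    receptor_coords = rbind(
      c(0, 0, 0), c(0, 0, 1.5), c(1.2, 0, 2.3)
    ),
    ligand_coords = rbind(
      c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.2, 0)
    )
  )
}

#' Monte Carlo confinement free energy
#'
#' Estimates the standard-state release free energy of a restraint on rigid
#' anchors by uniform importance sampling: translations uniform within a
#' bounding box of volume `V_box` chosen to cover the restrained region, and
#' orientations uniform over the rotation group. Then
#'
#' \deqn{\hat Z_r = 8\pi^2 V_{box} \langle e^{-\beta U}\rangle, \quad
#'   \Delta G = -k_B T \ln(8\pi^2 V^\circ / \hat Z_r)}
#'
#' with the standard error propagated from the Monte Carlo error of the mean
#' Boltzmann weight. The box spans the minimum-energy region plus
#' `r_fb + 8 sigma_eff` per axis, `sigma_eff = sqrt(kT / K_min)`, which
#' covers Gaussian-tailed integrands; if non-negligible density is found in
#' the outermost shell of the box a coverage error is raised.
#'
#' This estimator is deliberately independent of the quadrature routes and
#' serves as their stochastic oracle: each deterministic route should agree
#' with it within ~3 standard errors.
#'
#' @param x A [boresch_restraint()] or [distance_restraint_set()].
#' @param geometry A [rigid_anchor_geometry()]; defaults to
#'   [boresch_reference_geometry()] for Boresch restraints.
#' @param context A [thermo_context()].
#' @param samples Number of Monte Carlo samples. Default 2e5.
#' @param seed Integer seed; fixes the estimate exactly.
#' @return One-row tibble of class `mc_estimate`: `value` (kcal mol⁻¹),
#'   `se` (standard error), `samples`, `seed`, `method`.
#' @export
mc_confinement_free_energy <- function(x, geometry = NULL,
                                       context = thermo_context(),
                                       samples = 2e5, seed = 1L) {
  UseMethod("mc_confinement_free_energy")
}

#' @export
mc_confinement_free_energy.boresch_restraint <- function(x, geometry = NULL,
                                                         context = thermo_context(),
                                                         samples = 2e5,
                                                         seed = 1L) {
  context <- as_thermo_context(context)
  geometry <- geometry %||% boresch_reference_geometry(x)
  k <- x$force_constants
  if (k[["r"]] <= 0) {
    stop("restraint does not confine the ligand (k_r = 0)", call. = FALSE)
  }
  rec <- geometry$receptor_coords
  origin <- geometry$ligand_coords[1, ]
  off <- sweep(geometry$ligand_coords, 2, origin) # A at origin
  sigma_eff <- sqrt(context$kT / k[["r"]])
  reach <- x$equilibrium[["r"]] + 8 * sigma_eff
  bounds <- cbind(rec[1, ] - reach, rec[1, ] + reach)
  energy <- function(t, eu) {
    oB <- .euler_apply(eu$phi, eu$theta, eu$psi, off[2, ])
    oC <- .euler_apply(eu$phi, eu$theta, eu$psi, off[3, ])
    dof <- .boresch_dof_mat(
      a = rec[1, , drop = FALSE], b = rec[2, , drop = FALSE],
      c = rec[3, , drop = FALSE],
      A = t, B = t + oB, C = t + oC
    )
    boresch_energy(x, dof)
  }
  .mc_estimate(energy, bounds, context, samples, seed, "mc_boresch")
}

#' @export
mc_confinement_free_energy.distance_restraint_set <- function(x,
                                                              geometry,
                                                              context = thermo_context(),
                                                              samples = 2e5,
                                                              seed = 1L) {
  context <- as_thermo_context(context)
  r <- x$restraints
  if (all(r$K == 0)) {
    stop("restraint set does not confine the ligand (all K = 0)",
      call. = FALSE
    )
  }
  ri <- match(r$receptor_atom, geometry$receptor_atoms)
  li <- match(r$ligand_atom, geometry$ligand_atoms)
  if (anyNA(ri) || anyNA(li)) {
    stop("geometry does not cover all atoms referenced by the set",
      call. = FALSE
    )
  }
  origin <- colMeans(geometry$ligand_coords)
  off <- sweep(geometry$ligand_coords[li, , drop = FALSE], 2, origin)
  p <- geometry$receptor_coords[ri, , drop = FALSE]
  sigma_eff <- sqrt(context$kT / min(r$K[r$K > 0]))
  reach <- .row_norm(off) + r$r0 + r$r_fb + 8 * sigma_eff
  lo <- apply(p - reach, 2, max) # intersection of per-restraint reaches
  hi <- apply(p + reach, 2, min)
  if (any(hi <= lo)) { # inconsistent restraints: fall back to the union box
    lo <- apply(p - reach, 2, min)
    hi <- apply(p + reach, 2, max)
  }
  energy <- function(t, eu) {
    e <- 0
    for (n in seq_len(nrow(p))) {
      o <- .euler_apply(eu$phi, eu$theta, eu$psi, off[n, ])
      d <- sqrt(
        (t[, 1] + o[, 1] - p[n, 1])^2 +
          (t[, 2] + o[, 2] - p[n, 2])^2 +
          (t[, 3] + o[, 3] - p[n, 3])^2
      )
      e <- e + .pair_energy(d, r$r0[n], r$r_fb[n], r$K[n])
    }
    e
  }
  .mc_estimate(energy, cbind(lo, hi), context, samples, seed, "mc_mdr")
}

.mc_estimate <- function(energy, bounds, context, samples, seed, method) {
  samples <- as.integer(samples)
  w <- withr::with_seed(seed, {
    t <- cbind(
      stats::runif(samples, bounds[1, 1], bounds[1, 2]),
      stats::runif(samples, bounds[2, 1], bounds[2, 2]),
      stats::runif(samples, bounds[3, 1], bounds[3, 2])
    )
    eu <- .sample_euler(samples)
    list(w = exp(-context$beta * energy(t, eu)), t = t)
  })
  # coverage: the outermost 2% shell of the box must hold negligible density
  frac <- sweep(
    sweep(w$t, 2, bounds[, 1]), 2, bounds[, 2] - bounds[, 1], "/"
  )
  shell <- apply(frac < 0.02 | frac > 0.98, 1, any)
  if (any(shell) && max(w$w) > 0 &&
    max(w$w[shell]) > 1e-6 * max(w$w)) {
    stop(paste(
      "bounding region clips non-negligible Boltzmann density;",
      "enlarge the box"
    ), call. = FALSE)
  }
  mw <- mean(w$w)
  if (mw <= 0) stop("no sample carried Boltzmann weight", call. = FALSE)
  V_box <- prod(bounds[, 2] - bounds[, 1])
  Z <- 8 * pi^2 * V_box * mw
  se_mw <- stats::sd(w$w) / sqrt(samples)
  out <- tibble::tibble(
    value = -context$kT * log(8 * pi^2 * context$standard_volume / Z),
    se = context$kT * se_mw / mw,
    samples = samples, seed = as.integer(seed), method = method
  )
  class(out) <- c("mc_estimate", class(out))
  out
}
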