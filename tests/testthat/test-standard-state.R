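# Standard-state release free energies: frozen brute-force oracle values,
# closed-form limits, scaling laws, and cross-route equivalences.

ctx <- thermo_context()

make_boresch <- function(k = rep(10, 6), r0 = 5, thA = pi / 2, thB = pi / 2,
                         phis = c(0, 0, 0)) {
  boresch_restraint(
    r0 = r0, theta_A0 = thA, theta_B0 = thB,
    phi_A0 = phis[1], phi_B0 = phis[2], phi_C0 = phis[3],
    k_r = k[1], k_theta_A = k[2], k_theta_B = k[3],
    k_phi_A = k[4], k_phi_B = k[5], k_phi_C = k[6]
  )
}

test_that("Boresch release matches frozen brute-force quadrature values", {
  # Independently computed by plain composite-Simpson sums (20001+ nodes)
  # for all K = 10, r0 = 5 A, theta0 = 90 deg at 298 K, V° = 1660 A^3.
  br <- make_boresch()
  num <- boresch_release_numeric(br, ctx)
  ana <- boresch_release_analytic(br, ctx)
  expect_equal(num$value, -6.861890, tolerance = 1e-5)
  expect_equal(ana$value, -6.828223, tolerance = 1e-6)
  expect_equal(num$method, "boresch_numeric")
  expect_lt(num$convergence_estimate, 1e-8)
  # the Gaussian approximation stays within the few-hundredths regime here
  expect_lt(abs(ana$value - num$value), 0.04)
})

test_that("analytic and numerical routes converge in the stiff limit", {
  br <- make_boresch(k = rep(1000, 6))
  num <- boresch_release_numeric(br, ctx)
  ana <- boresch_release_analytic(br, ctx)
  expect_equal(num$value, -15.009923, tolerance = 1e-5) # frozen oracle
  expect_lt(abs(ana$value - num$value), 1e-3)
})

test_that("single-distance release matches its frozen oracle", {
  res <- single_distance_release(list(r0 = 3, r_fb = 0, K = 40), ctx)
  expect_equal(res$value, -2.293035, tolerance = 1e-5)
})

test_that("a hard flat well of standard-state volume releases for free", {
  # 4/3 pi (7.34)^3 = 1656 A^3, within a quarter percent of V° = 1660 A^3
  res <- single_distance_release(list(r0 = 0, r_fb = 7.34, K = Inf), ctx)
  expect_equal(res$value, -0.001270, tolerance = 1e-3)
  # hand-checked hard shell: I = (hi^3 - lo^3) / 3
  shell <- single_distance_release(list(r0 = 5, r_fb = 1, K = Inf), ctx)
  I <- (6^3 - 4^3) / 3
  expect_equal(shell$value, -ctx$kT * log(1660 / (4 * pi * I)))
})

test_that("unbounded integrals are refused", {
  expect_error(single_distance_release(list(r0 = 3, r_fb = 0, K = 0)), "unbounded")
  expect_error(
    single_distance_release(list(r0 = 3, r_fb = Inf, K = 40)),
    "unbounded"
  )
  expect_error(
    boresch_release_numeric(make_boresch(k = c(0, rep(10, 5)))),
    "k_r"
  )
  expect_error(
    boresch_release_analytic(make_boresch(k = c(10, 0, rep(10, 4)))),
    "zero force constants"
  )
  two <- distance_restraint_set(data.frame(
    receptor_atom = 1:2, ligand_atom = 3:4, r0 = 3, r_fb = 0, K = 40
  ))
  expect_error(single_distance_release(two, ctx), "exactly one")
})

test_that("release obeys the standard-volume scaling law -kT log(c)", {
  br <- make_boresch()
  for (c_fac in c(2, 10)) {
    big <- thermo_context(standard_volume = 1660 * c_fac)
    shift <- -ctx$kT * log(c_fac)
    expect_equal(
      boresch_release_numeric(br, big)$value -
        boresch_release_numeric(br, ctx)$value,
      shift,
      tolerance = 1e-9
    )
    expect_equal(
      boresch_release_analytic(br, big)$value -
        boresch_release_analytic(br, ctx)$value,
      shift,
      tolerance = 1e-12
    )
    sd0 <- list(r0 = 3, r_fb = 0, K = 40)
    expect_equal(
      single_distance_release(sd0, big)$value -
        single_distance_release(sd0, ctx)$value,
      shift,
      tolerance = 1e-9
    )
  }
})

test_that("scaling all six force constants shifts the analytic form by -3 kT log(c)", {
  br <- make_boresch()
  for (c_fac in c(4, 64)) {
    expect_equal(
      boresch_release_analytic(scale_restraints(br, 1), ctx)$value -
        boresch_release_analytic(make_boresch(k = rep(10 * c_fac, 6)), ctx)$value,
      3 * ctx$kT * log(c_fac),
      tolerance = 1e-10
    )
  }
})

test_that("-dG_release grows monotonically with every force constant", {
  base <- rep(8, 6)
  for (i in 1:6) {
    vals <- vapply(c(4, 8, 16, 32), function(k) {
      kk <- base
      kk[i] <- k
      boresch_release_numeric(make_boresch(k = kk), ctx)$value
    }, numeric(1))
    expect_true(all(diff(vals) < 0)) # dG_release down, -dG_release up
  }
})

test_that("zeroing the orientational trio leaves the positional-only integral", {
  # with theta_B, phi_B, phi_C free the orientational factor is exactly
  # 8 pi^2; check against independent adaptive quadrature (stats::integrate)
  k <- c(20, 15, 0, 12, 0, 0)
  br <- make_boresch(k = k, r0 = 4, thA = 1.2)
  got <- boresch_release_numeric(br, ctx)$value
  beta <- ctx$beta
  I_r <- stats::integrate(
    function(r) r^2 * exp(-beta * 0.5 * 20 * (r - 4)^2), 0, 20,
    rel.tol = 1e-10
  )$value
  I_th <- stats::integrate(
    function(th) sin(th) * exp(-beta * 0.5 * 15 * (th - 1.2)^2), 0, pi,
    rel.tol = 1e-10
  )$value
  I_ph <- stats::integrate(
    function(d) exp(-beta * 0.5 * 12 * d^2), -pi, pi,
    rel.tol = 1e-10
  )$value
  Z <- I_r * I_th * I_ph * (2 * (2 * pi) * (2 * pi)) # free trio Jacobian
  expect_equal(got, -ctx$kT * log(8 * pi^2 * 1660 / Z), tolerance = 1e-7)
})

test_that("a Boresch restraint on r alone equals the single-distance form", {
  for (p in list(c(40, 3), c(10, 5), c(120, 2))) {
    br <- make_boresch(k = c(p[1], 0, 0, 0, 0, 0), r0 = p[2])
    expect_equal(
      boresch_release_numeric(br, ctx)$value,
      single_distance_release(list(r0 = p[2], r_fb = 0, K = p[1]), ctx)$value,
      tolerance = 1e-7
    )
  }
})

test_that("the Euler grid integrates the Haar measure", {
  # the midpoint sum of sin(theta) has the closed form (pi/m) / sin(pi/(2m));
  # psi and phi midpoint sums are exact, so the node weights must total
  # (2 pi)^2 (pi/m) / sin(pi/(2m)), converging to 8 pi^2 quadratically
  total <- function(n) sum(abfer:::.euler_nodes(n)$weight)
  m <- 6 # theta nodes for orientations = 12
  expect_equal(total(12), (2 * pi)^2 * (pi / m) / sin(pi / (2 * m)),
    tolerance = 1e-12
  )
  err <- function(n) abs(total(n) - 8 * pi^2)
  expect_lt(err(12) / (8 * pi^2), 0.02)
  expect_lt(err(24), err(12) / 3) # second-order convergence
})

test_that("rigid-body grid release reproduces the closed single-distance form", {
  set <- distance_restraint_set(
    data.frame(receptor_atom = 1, ligand_atom = 2, r0 = 3, r_fb = 0.5, K = 40)
  )
  geo <- rigid_anchor_geometry(
    receptor_coords = rbind(c(0, 0, 0)),
    ligand_coords = rbind(c(3, 0, 0)),
    receptor_atoms = 1, ligand_atoms = 2
  )
  res <- rigid_body_release(
    set, geo, orientation_grid(element = 0.3, buffer = 2, orientations = 6),
    ctx,
    refine = TRUE
  )
  closed <- single_distance_release(set, ctx)
  expect_equal(res$method, "rigid_mdr_grid")
  # agreement within the grid's own convergence estimate (plus a floor)
  expect_lt(
    abs(res$value - closed$value),
    max(2 * res$convergence_estimate, 0.02)
  )
})

test_that("rigid-body grid release matches Boresch quadrature on rigid anchors", {
  br <- make_boresch(
    k = rep(8, 6), r0 = 3, thA = pi / 2, thB = 1.9,
    phis = c(0.5, -2, 2.5)
  )
  geo <- boresch_reference_geometry(br)
  res <- rigid_body_release(
    br, geo,
    orientation_grid(element = 0.45, buffer = 1.7, orientations = 12),
    ctx,
    refine = FALSE
  )
  num <- boresch_release_numeric(br, ctx)
  expect_equal(res$method, "rigid_boresch_grid")
  # tolerance matched to this grid resolution (calibrated headroom over the
  # observed ~0.002 kcal/mol deviation)
  expect_lt(abs(res$value - num$value), 0.05)
})

test_that("density touching the translation boundary raises an error", {
  set <- distance_restraint_set(
    data.frame(receptor_atom = 1, ligand_atom = 2, r0 = 3, r_fb = 0, K = 40)
  )
  geo <- rigid_anchor_geometry(
    receptor_coords = rbind(c(0, 0, 0)),
    ligand_coords = rbind(c(3, 0, 0)),
    receptor_atoms = 1, ligand_atoms = 2
  )
  tight <- orientation_grid(
    element = 0.3, orientations = 6,
    bounds = cbind(c(-3, -3, -3), c(3, 3, 3))
  )
  expect_error(rigid_body_release(set, geo, tight, ctx), "boundary")
})

test_that("grids validate their parameters and geometry coverage", {
  expect_error(orientation_grid(element = 0), "element")
  expect_error(orientation_grid(orientations = 2), "orientations")
  set <- distance_restraint_set(
    data.frame(receptor_atom = 9, ligand_atom = 2, r0 = 3, r_fb = 0, K = 40)
  )
  geo <- rigid_anchor_geometry(
    rbind(c(0, 0, 0)), rbind(c(3, 0, 0)),
    receptor_atoms = 1, ligand_atoms = 2
  )
  expect_error(rigid_body_release(set, geo, orientation_grid(), ctx), "cover")
})

test_that("release-to-single schedules free every restraint but one", {
  set <- distance_restraint_set(data.frame(
    receptor_atom = 1:3, ligand_atom = 4:6,
    r0 = c(3, 4, 5), r_fb = 0, K = c(10, 50, 20)
  ))
  sch <- release_to_single_schedule(set, n_windows = 11)
  expect_equal(sch$keep, 2) # defaults to the stiffest restraint
  expect_equal(sch$sets[[1]]$restraints$K, c(10, 50, 20)) # lambda = 0
  last <- sch$sets[[11]]$restraints$K # lambda = 1
  expect_equal(last, c(0, 50, 0))
  mid <- sch$sets[[6]]$restraints$K # lambda = 0.5, (1 - lambda)^5 scaling
  expect_equal(mid, c(10 * 0.5^5, 50, 20 * 0.5^5))
  expect_error(release_to_single_schedule(set, keep = 7), "keep")
})
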