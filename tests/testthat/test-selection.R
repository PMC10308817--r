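# Restraint selection: pair statistics, greedy anchor assignment, Boresch
# candidate enumeration, force-constant and flat-bottom fitting.

ctx <- thermo_context()

# Two parallel zigzag 4-atom chains (receptor below, ligand above), with the
# (2, 6) pair engineered to fluctuate least.
two_chain_spec <- function(pair_sd = 0.05, sigma = 0.15, n_frames = 300,
                           seed = 11) {
  mean_coords <- rbind(
    c(0, 0, 0), c(1.4, 0.6, 0), c(2.8, 0, 0), c(4.2, 0.6, 0),
    c(0, 0, 4), c(1.4, 0.6, 4), c(2.8, 0, 4), c(4.2, 0.6, 4)
  )
  atoms <- tibble::tibble(
    name = paste0("C", 1:8), element = "C",
    molecule = rep(c("receptor", "ligand"), each = 4)
  )
  synthetic_trajectory_spec(
    mean_coords, atoms,
    sigma = sigma,
    pairs = data.frame(i = 2, j = 6, sd = pair_sd),
    n_frames = n_frames, seed = seed
  )
}

test_that("pair statistics reproduce hand-computed means and SDs", {
  coords <- array(0, c(3, 3, 3))
  # receptor atom 1 at origin; ligand atom 2 at x = 3, 4, 5; ligand atom 3
  # fixed at x = 6
  coords[, 2, 1] <- c(3, 4, 5)
  coords[, 3, 1] <- 6
  traj <- md_trajectory(coords, tibble::tibble(
    name = c("C1", "C2", "C3"), element = "C",
    molecule = c("receptor", "ligand", "ligand")
  ))
  stats <- pair_distance_stats(traj)
  expect_s3_class(stats, "trajectory_stats")
  fixed <- stats[stats$ligand_atom == 3, ]
  moving <- stats[stats$ligand_atom == 2, ]
  expect_equal(fixed$mean, 6)
  expect_equal(fixed$sd, 0)
  expect_equal(moving$mean, 4)
  expect_equal(moving$sd, 1)
  # sorted ascending by SD: the rigid pair ranks first
  expect_equal(stats$ligand_atom[1], 3)
})

test_that("the first-frame contact cutoff excludes distant receptor atoms", {
  coords <- array(0, c(2, 3, 3))
  coords[, 2, 1] <- 50 # second receptor atom far away
  coords[, 3, 1] <- c(3, 3.1) # ligand near atom 1
  traj <- md_trajectory(coords, tibble::tibble(
    name = c("C1", "C2", "C3"), element = "C",
    molecule = c("receptor", "receptor", "ligand")
  ))
  stats <- pair_distance_stats(traj, contact_cutoff = 10)
  expect_false(2 %in% stats$receptor_atom)
  expect_error(
    pair_distance_stats(traj, receptor_atoms = 2, contact_cutoff = 10),
    "contact cutoff"
  )
})

test_that("variance is refused for a single frame and top_n truncates", {
  spec <- two_chain_spec(n_frames = 40)
  traj <- generate_synthetic_trajectory(spec)
  one <- md_trajectory(traj$coords[1, , , drop = FALSE], traj$atoms)
  expect_error(pair_distance_stats(one), "2 frames")
  expect_equal(nrow(pair_distance_stats(traj, top_n = 5)), 5)
})

test_that("an engineered low-variance pair ranks first", {
  traj <- generate_synthetic_trajectory(two_chain_spec())
  stats <- pair_distance_stats(traj)
  expect_equal(stats$receptor_atom[1], 2)
  expect_equal(stats$ligand_atom[1], 6)
  # and its observed SD is close to the engineered target
  truth <- attr(traj, "truth")$pairs
  expect_equal(stats$sd[1], truth$observed_sd[1])
})

test_that("greedy selection keeps each atom as anchor of at most one pair", {
  stats <- tibble::tibble(
    receptor_atom = c(1, 1, 2, 2, 3),
    ligand_atom = c(11, 12, 11, 12, 13),
    mean = c(3, 4, 5, 6, 7),
    sd = c(0.1, 0.2, 0.3, 0.4, 0.5)
  )
  set <- select_distance_restraints(stats)
  kept <- set$restraints
  # (1,11) kept; (1,12) and (2,11) blocked; (2,12) and (3,13) kept
  expect_equal(kept$receptor_atom, c(1, 2, 3))
  expect_equal(kept$ligand_atom, c(11, 12, 13))
  expect_equal(kept$r0, c(3, 6, 7))
  expect_true(all(is.na(kept$K)))
  expect_true(all(kept$r_fb == 0))
  all_atoms <- c(kept$receptor_atom, kept$ligand_atom)
  expect_equal(anyDuplicated(all_atoms), 0L)
})

test_that("fully disjoint candidate pairs are all retained", {
  n <- 22
  stats <- tibble::tibble(
    receptor_atom = seq_len(n), ligand_atom = 100 + seq_len(n),
    mean = runif(n, 3, 8), sd = sort(runif(n, 0.05, 0.5))
  )
  set <- select_distance_restraints(stats)
  expect_equal(nrow(set$restraints), n)
})

test_that("bond inference links covalent neighbours within one molecule", {
  traj <- generate_synthetic_trajectory(two_chain_spec(n_frames = 2, sigma = 0))
  bonds <- infer_bonds(traj)
  # chain bonds only: 1-2, 2-3, 3-4 and 5-6, 6-7, 7-8
  expect_equal(nrow(bonds), 6)
  expect_true(all(bonds$j - bonds$i == 1))
  # no cross-molecule bonds
  mol <- traj$atoms$molecule
  expect_true(all(mol[bonds$i] == mol[bonds$j]))
})

test_that("circular statistics respect the dihedral topology", {
  cm <- abfer:::circular_mean
  cv <- abfer:::circular_var
  x <- c(-0.2, 0.1, 0.05, -0.1)
  # far from the wrap point, circular and linear statistics agree
  expect_lt(abs(cm(x) - mean(x)), 1e-3)
  expect_lt(abs(cv(x) - var(x)), 1e-3)
  # shifting by 2*pi changes nothing
  expect_equal(cv(x + 2 * pi), cv(x), tolerance = 1e-12)
  # a tight cluster straddling +/- pi has small circular variance even
  # though its linear variance is huge
  y <- c(pi - 0.05, -pi + 0.08, pi - 0.01, -pi + 0.03)
  expect_lt(cv(y), 0.01)
  expect_gt(var(y), 1)
})

test_that("force-constant fitting inverts the thermal variance relation", {
  vars <- c(r = 0.04, theta_A = 0.01)
  k <- fit_force_constants(vars, ctx)
  expect_equal(unname(k), ctx$kT / unname(vars))
  expect_error(fit_force_constants(c(r = 0)), "infinite force constant")
})

test_that("fitted force constants recover the generating stiffness", {
  # target distance SD 0.2 A at 6 A separation: K_true = kT / sd^2
  sd_target <- 0.2
  k_true <- ctx$kT / sd_target^2
  spec <- synthetic_trajectory_spec(
    rbind(c(0, 0, 0), c(6, 0, 0)),
    tibble::tibble(
      name = c("C1", "C2"), element = "C",
      molecule = c("receptor", "ligand")
    ),
    pairs = data.frame(i = 1, j = 2, sd = sd_target),
    n_frames = 5000, seed = 3
  )
  traj <- generate_synthetic_trajectory(spec)
  stats <- pair_distance_stats(traj)
  k_fit <- fit_force_constants(c(r = stats$sd[1]^2), ctx)
  expect_lt(abs(k_fit[["r"]] - k_true) / k_true, 0.10)
})

test_that("Boresch enumeration completes anchors over bonds and ranks by variance", {
  traj <- generate_synthetic_trajectory(two_chain_spec())
  stats <- pair_distance_stats(traj)
  # the quietest pair heads the stats table; enumerate its completions
  cands <- enumerate_boresch_candidates(head(stats, 1), traj)
  expect_s3_class(cands, "boresch_candidates")
  expect_true(all(cands$a == 2 & cands$A == 6))
  expect_true(all(diff(cands$score) >= 0))
  # the angle filter holds for everything retained
  lo <- 30 * pi / 180
  hi <- 150 * pi / 180
  expect_true(all(cands$mean_theta_A >= lo & cands$mean_theta_A <= hi))
  expect_true(all(cands$mean_theta_B >= lo & cands$mean_theta_B <= hi))
  # anchors are chains of bonded atoms on the right molecules: b bonded to
  # a = 2, c bonded to b (and != a); mirrored on the ligand
  expect_true(all(cands$b %in% c(1, 3) & cands$B %in% c(5, 7)))
  expect_true(all(abs(cands$c - cands$b) == 1 & cands$c != 2))
  expect_true(all(abs(cands$C - cands$B) == 1 & cands$C != 6))
  # the direct score is exactly the sum of the six per-DoF variances
  vars <- as.matrix(cands[, paste0("var_", c(
    "r", "theta_A", "theta_B", "phi_A", "phi_B", "phi_C"
  ))])
  expect_equal(cands$score, unname(rowSums(vars)))
  # the engineered quiet pair contributes the smallest distance variance
  expect_lt(max(cands$var_r), min(stats$sd[-1]^2))
})

test_that("a fitted restraint matches the candidate statistics", {
  traj <- generate_synthetic_trajectory(two_chain_spec())
  stats <- pair_distance_stats(traj)
  cands <- enumerate_boresch_candidates(head(stats, 3), traj)
  br <- boresch_from_candidate(cands, context = ctx)
  expect_s3_class(br, "boresch_restraint")
  expect_equal(br$equilibrium[["r"]], cands$mean_r[1])
  expect_equal(br$force_constants[["r"]], ctx$kT / cands$var_r[1])
  expect_equal(
    br$force_constants[["phi_B"]], ctx$kT / cands$var_phi_B[1]
  )
  # right-angled, stiff anchors: far from collinearity
  expect_false(attr(br, "collinearity_flagged"))
  expect_gt(attr(br, "collinearity_penalty"), 10 * ctx$kT)
})

test_that("collinearity penalty is the cheapest route to a straight angle", {
  expect_equal(
    collinearity_penalty(10, pi / 2, 10, pi / 2),
    0.5 * 10 * (pi / 2)^2
  )
  # an off-centre angle is closest to the nearer of 0 and pi
  expect_equal(
    collinearity_penalty(10, 2.8, 1000, pi / 2),
    0.5 * 10 * (pi - 2.8)^2
  )
  # a floppy angle makes the restraint cheap to straighten
  expect_equal(collinearity_penalty(0, pi / 2, 10, pi / 2), 0)
  # vectorised
  expect_length(collinearity_penalty(c(10, 20), pi / 2, 10, pi / 2), 2)
})

test_that("max-excursion flat bottoms never engage on the fitting frames", {
  traj <- generate_synthetic_trajectory(two_chain_spec(n_frames = 80))
  stats <- pair_distance_stats(traj)
  set <- select_distance_restraints(stats)
  set$restraints$K <- 40
  fitted <- fit_flat_bottom_radii(set, traj, mode = "max_excursion")
  d <- pair_distance_series(
    traj,
    data.frame(
      i = fitted$restraints$receptor_atom,
      j = fitted$restraints$ligand_atom
    )
  )
  expect_equal(distance_set_energy(fitted, d), rep(0, traj$n_frames))
  # percentile radii are no larger than the maximum excursion
  p50 <- fit_flat_bottom_radii(set, traj, mode = "percentile", percentile = 50)
  expect_true(all(p50$restraints$r_fb <= fitted$restraints$r_fb))
  expect_true(any(distance_set_energy(p50, d) > 0))
})
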