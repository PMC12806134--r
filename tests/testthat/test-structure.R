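test_that("lateral area statistics use the population SD", {
  traj <- make_straight_chain_traj(c(0, 0, 1), n_mol = 4L)
  traj$coords <- array(rep(traj$coords, 4), c(n_atoms(traj), 3L, 4L))
  traj$box <- matrix(rep(c(5, 5, 10), each = 4), 4, 3L)
  traj$time <- (0:3) * 100
  # series {70, 71, 69, 70}: mean 70, population SD sqrt(0.5)
  traj$box[, 1L] <- c(70, 71, 69, 70) / 5
  leaf <- assign_leaflets(traj)
  st <- lateral_area_stats(traj, leaf)
  expect_equal(st$mean, 70)
  expect_equal(st$sd, sqrt(0.5), tolerance = 1e-12)
  expect_equal(unname(st$apl[["outer"]]), 70 / 2)  # 2 lipids per leaflet
  # constant box: SD exactly 0
  traj$box[, 1L] <- 8.4; traj$box[, 2L] <- 8.4
  st2 <- lateral_area_stats(traj, leaf)
  expect_equal(st2$mean, 70.56)
  expect_identical(st2$sd, 0)
})

test_that("density profiles conserve total mass and charge for any binning", {
  set.seed(9)
  g <- generate_bilayer_trajectory(
    bilayer_spec(n_lipids = c(outer = 8L, inner = 8L), water_count = 40,
                 box = c(3.4, 3.4, 8), seed = 31), 4)
  traj <- g$trajectory
  at <- traj$topology$atoms
  for (bw in c(0.05, 0.1, 0.23)) {
    for (sel in list(seq_len(n_atoms(traj)),
                     select_atoms(traj, role = "water_oxygen"))) {
      prof <- density_profile(traj, sel, bin_width = bw, weight = "mass")
      integral <- sum(prof$density) * attr(prof, "bin_width") * attr(prof, "area")
      expect_equal(integral, sum(at$mass[sel]), tolerance = 1e-6)
    }
  }
  # charge weight on a neutral selection integrates to ~0
  qp <- density_profile(traj, seq_len(n_atoms(traj)), weight = "charge")
  qint <- sum(qp$density) * attr(qp, "bin_width") * attr(qp, "area")
  expect_equal(qint, sum(at$charge), tolerance = 1e-9)
  expect_error(density_profile(traj, integer(0)), "empty")
})

test_that("uniform waters give a flat profile at N m / (A w)", {
  set.seed(3)
  n <- 4000L
  topo <- make_water_topology(n)
  coords <- array(NA_real_, c(n, 3L, 1L))
  coords[, 1L, 1L] <- runif(n, 0, 5); coords[, 2L, 1L] <- runif(n, 0, 5)
  coords[, 3L, 1L] <- runif(n, -2, 2)          # 4 nm slab
  traj <- trajectory(topo, coords, c(5, 5, 10))
  prof <- density_profile(traj, seq_len(n), bin_width = 0.5)
  expected <- n * 18.015 / (25 * 4)
  inslab <- abs(prof$z) < 1.7
  expect_equal(mean(prof$density[inslab]), expected, tolerance = 0.02)
  expect_lt(max(abs(prof$density[inslab] - expected)) / expected, 0.12)
})

test_that("membrane thickness finds refined peaks and rejects degenerate profiles", {
  # synthetic triangular peaks centred exactly at +/- 2.0 nm on bin centers
  prof <- make_charge_profile(function(z)
    pmax(0, 1 - abs(abs(z) - 2) / 0.3), zmax = 4, bin_width = 0.1)
  attr(prof, "weight") <- "mass"
  expect_equal(membrane_thickness(prof), 4.0, tolerance = 1e-9)
  # invariance under rescaling
  prof2 <- prof; prof2$density <- prof2$density * 7.3
  expect_equal(membrane_thickness(prof2), membrane_thickness(prof))
  # invariance under z-reflection
  prof3 <- prof
  prof3$density <- rev(prof3$density)
  expect_equal(membrane_thickness(prof3), membrane_thickness(prof),
               tolerance = 1e-9)
  # monotone side: no leaflet peak
  prof4 <- make_charge_profile(function(z) exp(z), zmax = 3, bin_width = 0.1)
  expect_error(membrane_thickness(prof4), "no leaflet peak")
})

test_that("tilt angle conventions anchor at 0 (in-plane) and 90 (normal)", {
  traj_z <- make_straight_chain_traj(c(0, 0, 1), n_mol = 2L)
  leaf <- assign_leaflets(traj_z)
  t_z <- tilt_distribution(traj_z, "TST", leaf, "outer", bin_width = 1)
  expect_equal(t_z$mode_deg, 89.5, tolerance = 1)   # top bin center
  traj_x <- make_straight_chain_traj(c(1, 0, 0), n_mol = 2L)
  t_x <- tilt_distribution(traj_x, "TST", assign_leaflets(traj_x), "outer")
  expect_equal(t_x$mode_deg, 0.5, tolerance = 1)    # bottom bin center
  expect_error(tilt_distribution(traj_z, "NOPE", leaf, "outer"), "not present")
})

test_that("order parameters hit the closed-form anchors", {
  leafget <- function(tr) assign_leaflets(tr)
  # all chords parallel to z: S_CD = 1 at every carbon
  tr1 <- make_straight_chain_traj(c(0, 0, 1), n_mol = 4L)
  o1 <- chain_order_parameters(tr1, "TST", 1L, leafget(tr1), "outer")
  expect_equal(o1$scd, rep(1, nrow(o1)), tolerance = 1e-12)
  # all chords in-plane: S_CD = -0.5
  tr2 <- make_straight_chain_traj(c(1, 0, 0), n_mol = 4L)
  o2 <- chain_order_parameters(tr2, "TST", 1L, leafget(tr2), "outer")
  expect_equal(o2$scd, rep(-0.5, nrow(o2)), tolerance = 1e-12)
  # magic angle: S_CD = 0
  ma <- 54.7356103172453 * pi / 180
  tr3 <- make_straight_chain_traj(c(sin(ma), 0, cos(ma)), n_mol = 4L)
  o3 <- chain_order_parameters(tr3, "TST", 1L, leafget(tr3), "outer")
  expect_lt(max(abs(o3$scd)), 1e-6)
  # too-short chains are rejected
  short <- make_straight_chain_traj(c(0, 0, 1), n_carbons = 3L)
  expect_error(chain_order_parameters(short, "TST", 1L, leafget(short), "outer"),
               "fewer than 3")
})

test_that("order profile differences subtract elementwise", {
  tr1 <- make_straight_chain_traj(c(0, 0, 1), n_mol = 4L)
  tr2 <- make_straight_chain_traj(c(1, 0, 0), n_mol = 4L)
  leaf <- assign_leaflets(tr1)
  a <- chain_order_parameters(tr1, "TST", 1L, leaf, "outer")
  b <- chain_order_parameters(tr2, "TST", 1L, assign_leaflets(tr2), "outer")
  d <- scd_difference(a, b)
  expect_equal(d$dscd, rep(1.5, nrow(d)), tolerance = 1e-12)
  expect_equal(scd_difference(a, a)$dscd, rep(0, nrow(a)))
})

test_that("generator ground truth is recovered by the structural observables", {
  g <- generate_bilayer_trajectory(
    bilayer_spec(n_lipids = c(outer = 30L, inner = 30L), water_count = 100,
                 headgroup_peak_z = 1.8, seed = 99,
                 tilt_mode_deg = c(default = 70, CHOL = 76)), 60)
  traj <- g$trajectory
  leaf <- assign_leaflets(traj)
  heads <- select_atoms(traj, role = "headgroup_ref")
  thick <- membrane_thickness(density_profile(traj, heads, bin_width = 0.1))
  expect_equal(thick, 3.6, tolerance = 0.1 / 3.6)      # within 1 bin
  tl <- tilt_distribution(traj, "CHOL", leaf, "outer")
  expect_equal(tl$mode_deg, 76, tolerance = 1 / 76)    # within 1 degree
})
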