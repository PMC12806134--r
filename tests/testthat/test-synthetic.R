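test_that("identical seeds give bit-identical trajectories", {
  spec <- bilayer_spec(n_lipids = c(outer = 8L, inner = 8L), water_count = 30,
                       box = c(3.2, 3.2, 7), seed = 77)
  a <- generate_bilayer_trajectory(spec, 5)
  b <- generate_bilayer_trajectory(spec, 5)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$trajectory$box, b$trajectory$box)
  spec2 <- spec; spec2$seed <- 78L
  c <- generate_bilayer_trajectory(spec2, 5)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
})

test_that("generated systems are charge-balanced when sheets sum to zero", {
  spec <- bilayer_spec(charge_profile = data.frame(z = c(-1, 1),
                                                   sigma = c(0.02, -0.02)),
                       n_lipids = c(outer = 10L, inner = 10L),
                       water_count = 20, box = c(3.5, 3.5, 8), seed = 4)
  g <- generate_bilayer_trajectory(spec, 1)
  expect_equal(sum(g$trajectory$topology$atoms$charge), 0, tolerance = 1e-9)
})

test_that("generator output is a valid trajectory consumable by the writers", {
  g <- generate_bilayer_trajectory(
    bilayer_spec(n_lipids = c(outer = 5L, inner = 5L), water_count = 10,
                 box = c(3, 3, 7), seed = 10), 2)
  f <- withr::local_tempfile(fileext = ".gro")
  expect_no_error(write_coordinates(g$trajectory, f, "gro"))
  back <- read_coordinates(f, "gro")
  expect_equal(n_atoms(back), n_atoms(g$trajectory))
})

test_that("infeasible specs are rejected", {
  expect_error(bilayer_spec(target_scd = list(`16` = rep(1.2, 15L))),
               "\\[-0.5, 1\\]")
  expect_error(bilayer_spec(composition = list(outer = c(POPC = 0.7),
                                               inner = c(POPC = 1))),
               "sum to 1")
  expect_error(bilayer_spec(headgroup_peak_z = -1), "headgroup_peak_z")
  # lattice overflow: explicit box too small for the lipid area
  spec <- bilayer_spec(n_lipids = c(outer = 100L, inner = 100L),
                       box = c(3, 3, 10))
  expect_error(generate_bilayer_trajectory(spec, 1), "lattice overflow")
})

test_that("area series has the prescribed stationary SD", {
  spec <- bilayer_spec(n_lipids = c(outer = 30L, inner = 30L),
                       water_count = 10, area_fluctuation_sd = 0.3,
                       seed = 15)
  g <- generate_bilayer_trajectory(spec, 400)
  a <- g$trajectory$box[, 1L] * g$trajectory$box[, 2L]
  expect_equal(sd(a), 0.3, tolerance = 0.35)  # AR(1): wide Monte-Carlo band
})

test_that("injected events construct monotone in-slab paths", {
  set.seed(6)
  traj <- make_quiescent_waters(6, 50)
  ev <- data.frame(water_id = c(1L, 2L), direction = c("outer_to_inner",
                                                       "inner_to_outer"),
                   entry_frame = c(10L, 25L), dwell_frames = c(8L, 5L))
  inj <- inject_permeation_events(traj, ev, bounds = c(-1.5, 1.5))
  z1 <- inj$trajectory$coords[1L, 3L, ]
  inside <- which(z1 > -1.5 & z1 < 1.5)
  expect_identical(inside, 10:17)
  expect_true(all(diff(z1[5:20]) < 0))      # monotone descent o->i
  expect_equal(inj$ground_truth$dwell_ns, c(0.8, 0.5))
  # error contracts
  expect_error(inject_permeation_events(traj, transform(ev, entry_frame = c(10L, 48L))),
               "exceed")
  expect_error(inject_permeation_events(
    traj, data.frame(water_id = 99L, direction = "outer_to_inner",
                     entry_frame = 5L, dwell_frames = 3L)), "not a water")
})

test_that("ideal gas stores the exact rho kT pressure and zero virial", {
  sys <- generate_pair_system(512, box = c(8, 8, 8), "ideal_gas",
                              temperature = 300, seed = 7)
  rho_kT_bar <- (512 / 512) * 0.0083144621 * 300 * 16.6054
  expect_equal(sys$pressure_bar, rho_kT_bar, tolerance = 1e-12)
  expect_equal(nrow(sys$pairs), 0L)
})

test_that("single-pair systems store the analytic pair force", {
  sys <- generate_pair_system(2, box = c(4, 4, 10), "single_pair",
                              epsilon = 0.8, sigma = 2.0, cutoff = 3.0,
                              positions = rbind(c(2, 2, 3.75), c(2, 2, 6.25)))
  p <- sys$pairs
  expect_equal(nrow(p), 1L)
  # purely z-directed by geometry
  expect_equal(p$fx, 0); expect_equal(p$fy, 0)
  r <- 2.5
  f_expect <- 24 * 0.8 / r * (2 * (2 / r)^12 - (2 / r)^6)
  expect_equal(abs(p$fz), abs(f_expect), tolerance = 1e-12)
  # attractive at r > 2^(1/6) sigma: force on i points toward j
  expect_lt(p$dz * p$fz, 0)
  # stored force equals the numerical derivative of the pair potential
  U <- function(r) 4 * 0.8 * ((2 / r)^12 - (2 / r)^6)
  f_num <- -(U(r + 1e-6) - U(r - 1e-6)) / 2e-6
  expect_equal(abs(p$fz), abs(f_num), tolerance = 1e-6)
})

test_that("bulk fluid placement enforces the minimum separation", {
  sys <- generate_pair_system(150, box = c(4, 4, 4), "bulk_fluid",
                              sigma = 0.34, seed = 12)
  expect_gt(min(sys$pairs$r), 0.1 * 0.34)
})
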