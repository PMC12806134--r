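test_that("a constructed single crossing is detected with exact dwell", {
  # monotone descent +3 -> -3 nm through bounds +/-1.5, 8 frames inside
  set.seed(11)
  traj <- make_quiescent_waters(4, 40, dt = 100)   # dt = 0.1 ns
  inj <- inject_permeation_events(
    traj, data.frame(water_id = 1L, direction = "outer_to_inner",
                     entry_frame = 12L, dwell_frames = 8L),
    bounds = c(-1.5, 1.5))
  reg <- hydrophobic_bounds(inj$trajectory, "explicit", bounds = c(-1.5, 1.5))
  ev <- detect_permeation_events(inj$trajectory, reg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "outer_to_inner")
  expect_equal(ev$dwell_ns, 0.8)
  expect_equal(ev$entry_frame, 12L)
  expect_equal(ev$exit_frame, 20L)
})

test_that("same-side retreats and periodic wraps emit no events", {
  reg <- list(hydrophobic_region(-1.5, 1.5))
  # dip to z = -0.5 then retreat through the same (upper) bound
  dip <- c(3, 2.5, 2, 1, -0.5, 0.2, 1.8, 2.5, 3, 3)
  # wrap through the periodic boundary of a 10 nm box: +4.9 -> -4.9
  wrap <- c(4.0, 4.5, 4.9, -4.9, -4.3, -4.0, -3.8, -3.5, -3.2, -3.0)
  traj <- make_water_traj(rbind(dip, wrap), box = c(5, 5, 10))
  ev <- detect_permeation_events(traj, reg)
  expect_equal(nrow(ev), 0L)
})

test_that("quiescent trajectories are free of false events", {
  set.seed(5)
  traj <- make_quiescent_waters(20, 120)
  reg <- list(hydrophobic_region(-1.5, 1.5))
  expect_equal(nrow(detect_permeation_events(traj, reg)), 0L)
})

test_that("mixed-direction injections are recovered with matching directions", {
  set.seed(8)
  traj <- make_quiescent_waters(10, 80)
  ev_in <- data.frame(
    water_id = 1:7,
    direction = c("outer_to_inner", "inner_to_outer", "outer_to_inner",
                  "outer_to_inner", "inner_to_outer", "inner_to_outer",
                  "outer_to_inner"),
    entry_frame = c(5L, 12L, 20L, 30L, 40L, 50L, 60L),
    dwell_frames = c(3L, 8L, 5L, 10L, 4L, 6L, 7L))
  inj <- inject_permeation_events(traj, ev_in, bounds = c(-1.5, 1.5))
  det <- detect_permeation_events(inj$trajectory,
                                  list(hydrophobic_region(-1.5, 1.5)))
  det <- det[order(det$water_id), ]
  expect_equal(nrow(det), 7L)
  expect_equal(det$direction, ev_in$direction)
  expect_equal(det$dwell_ns, ev_in$dwell_frames * 0.1)
  st <- dwell_time_stats(det)
  expect_equal(unname(st$counts), c(4L, 3L))
})

test_that("direction counts flip exactly under z-reflection", {
  set.seed(13)
  traj <- make_quiescent_waters(8, 60)
  ev_in <- data.frame(water_id = 1:4,
                      direction = c("outer_to_inner", "outer_to_inner",
                                    "inner_to_outer", "outer_to_inner"),
                      entry_frame = c(5L, 15L, 25L, 35L),
                      dwell_frames = c(4L, 6L, 3L, 8L))
  inj <- inject_permeation_events(traj, ev_in, bounds = c(-1.5, 1.5))
  reg <- list(hydrophobic_region(-1.5, 1.5))
  det <- detect_permeation_events(inj$trajectory, reg)
  det_r <- detect_permeation_events(reflect_z(inj$trajectory), reg)
  s <- dwell_time_stats(det)$counts
  s_r <- dwell_time_stats(det_r)$counts
  expect_identical(unname(s[["outer_to_inner"]]), unname(s_r[["inner_to_outer"]]))
  expect_identical(unname(s[["inner_to_outer"]]), unname(s_r[["outer_to_inner"]]))
  expect_equal(sort(det$dwell_ns), sort(det_r$dwell_ns))
})

test_that("event counts survive frame sub-sampling of monotone crossings", {
  set.seed(17)
  traj <- make_quiescent_waters(6, 80)
  ev_in <- data.frame(water_id = 1:3,
                      direction = c("outer_to_inner", "inner_to_outer",
                                    "outer_to_inner"),
                      entry_frame = c(10L, 30L, 50L), dwell_frames = c(6L, 8L, 4L))
  inj <- inject_permeation_events(traj, ev_in, bounds = c(-1.5, 1.5))
  reg <- list(hydrophobic_region(-1.5, 1.5))
  full <- detect_permeation_events(inj$trajectory, reg)
  sub <- inj$trajectory
  keep <- seq(1, 80, by = 2)
  sub$coords <- sub$coords[, , keep, drop = FALSE]
  sub$box <- sub$box[keep, , drop = FALSE]
  sub$time <- sub$time[keep]; sub$dt <- sub$dt * 2
  coarse <- detect_permeation_events(sub, reg)
  expect_equal(nrow(coarse), nrow(full))
  expect_equal(sort(coarse$direction), sort(full$direction))
})

test_that("tail-density bounds recover the generator's hydrophobic slab", {
  g <- generate_bilayer_trajectory(
    bilayer_spec(n_lipids = c(outer = 30L, inner = 30L), water_count = 60,
                 seed = 23), 20)
  reg <- hydrophobic_bounds(g$trajectory, "tail_density")
  expect_length(reg, 1L)
  expect_lt(reg[[1L]]$lower, -1)
  expect_gt(reg[[1L]]$upper, 1)
  expect_equal(reg[[1L]]$upper, -reg[[1L]]$lower, tolerance = 0.15)
  # explicit bounds pass through unchanged
  ex <- hydrophobic_bounds(g$trajectory, "explicit", bounds = c(-1.4, 1.4))
  expect_equal(ex[[1L]]$lower, -1.4)
  expect_equal(ex[[1L]]$upper, 1.4)
  # water-only trajectories carry no tail density
  wat <- make_quiescent_waters(5, 5)
  expect_error(hydrophobic_bounds(wat, "tail_density"), "no tail density")
})

test_that("ion selections show no permeation on quiescent systems", {
  g <- generate_bilayer_trajectory(
    bilayer_spec(n_lipids = c(outer = 10L, inner = 10L), water_count = 30,
                 box = c(3.5, 3.5, 8), seed = 29), 10)
  reg <- list(hydrophobic_region(-1.2, 1.2))
  ions <- select_atoms(g$trajectory, species = c("CAT", "ANI"))
  expect_gt(length(ions), 0L)   # PS counterions exist
  ev <- detect_permeation_events(g$trajectory, reg, selection = ions)
  expect_equal(nrow(ev), 0L)
})

test_that("dwell-time statistics bin and split by direction", {
  ev <- data.frame(water_id = 1:3, membrane = "membrane",
                   direction = c("outer_to_inner", "outer_to_inner",
                                 "inner_to_outer"),
                   entry_frame = c(1L, 5L, 9L), exit_frame = c(4L, 8L, 12L),
                   dwell_ns = c(0.8, 0.8, 0.8))
  st <- dwell_time_stats(ev, bin_width = 0.5)
  occupied <- st$histogram[st$histogram$count > 0, ]
  expect_equal(nrow(occupied), 1L)
  expect_equal(occupied$bin_lo, 0.5)
  expect_equal(occupied$bin_hi, 1.0)
  expect_equal(unname(st$counts), c(2L, 1L))
  empty <- dwell_time_stats(ev[0, ])
  expect_equal(unname(empty$counts), c(0L, 0L))
  expect_equal(nrow(empty$histogram), 0L)
})
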