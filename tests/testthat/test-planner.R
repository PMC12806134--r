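test_that("largest-remainder apportionment is exact and deterministic", {
  expect_identical(composition_counts(c(POPC = 0.55, PSM = 0.45), 40),
                   c(POPC = 22L, PSM = 18L))
  expect_identical(composition_counts(c(POPE = 0.5, POPC = 0.3, POPS = 0.2), 47),
                   c(POPE = 24L, POPC = 14L, POPS = 9L))
  expect_identical(composition_counts(c(A = 0.5, B = 0.5), 0), c(A = 0L, B = 0L))
  expect_error(composition_counts(c(A = -0.1, B = 1.1), 10), "negative")
  # exactness and per-species error < 1 for arbitrary inputs
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    f <- runif(k); f <- f / sum(f); names(f) <- paste0("S", seq_len(k))
    n <- sample(0:200, 1)
    ct <- composition_counts(f, n)
    expect_identical(sum(ct), n)
    expect_lt(max(abs(ct - f * n)), 1)
  }
})

test_that("area matching yields the printed 5-lipid offset with small residual", {
  # 0% CHOL leaflet pair: areas 70.7 vs 67.8 nm^2, phospholipid APL 0.6 nm^2
  amo <- area_match_offsets(70.7, 67.8, "outer",
                            apl = c(POPC = 0.6, PSM = 0.6),
                            fractions = c(POPC = 0.55, PSM = 0.45))
  expect_identical(amo$offset, -5L)          # outer is larger: remove 5
  expect_identical(sum(abs(amo$delta_counts)), 5L)
  expect_lte(amo$residual_area, 0.3)
  # 20% CHOL pair where the outer leaflet is *smaller* by 2.7 nm^2
  apl20 <- c(POPC = 0.6, PSM = 0.6, CHOL = 0.3)
  fr20 <- c(POPC = 0.44, PSM = 0.36, CHOL = 0.20)
  amo2 <- area_match_offsets(60.0, 62.7, "outer", apl20, fr20)
  expect_identical(amo2$offset, +5L)         # sign reversed: add 5
  # equal areas: no adjustment
  amo3 <- area_match_offsets(60, 60, "outer", apl20, fr20)
  expect_identical(amo3$offset, 0L)
  expect_identical(sum(abs(amo3$delta_counts)), 0L)
})

test_that("area matching leaves residual within half a mean area per lipid", {
  set.seed(7)
  for (i in 1:20) {
    ao <- runif(1, 45, 75); ai <- runif(1, 45, 75)
    fr <- c(POPC = 0.5, PSM = 0.3, CHOL = 0.2)
    apl <- c(POPC = 0.6, PSM = 0.6, CHOL = 0.3)
    amo <- area_match_offsets(ao, ai, "inner", apl, fr)
    expect_lte(amo$residual_area, amo$mean_apl / 2 + 1e-9)
  }
})

test_that("stress variants rescale only the outer leaflet", {
  outer <- leaflet_plan(c(POPC = 26L, PSM = 22L, CHOL = 12L))
  inner <- leaflet_plan(c(POPE = 24L, POPC = 14L, POPS = 10L, CHOL = 12L))
  plan <- assembly_plan(outer, inner, label = "H20")
  p5 <- stress_variant(plan, +5)
  expect_identical(sum(p5$outer$counts), 63L)    # 60 * 1.05
  m10 <- stress_variant(plan, -10)
  expect_identical(sum(m10$outer$counts), 54L)   # 60 * 0.90
  z <- stress_variant(plan, 0)
  expect_identical(z$outer$counts, plan$outer$counts)
  # inner leaflet untouched, fractions preserved within 1/total
  for (v in list(p5, m10)) {
    expect_identical(v$inner$counts, inner$counts)
    f0 <- plan$outer$counts / 60
    f1 <- v$outer$counts / sum(v$outer$counts)
    expect_lt(max(abs(f1 - f0[names(f1)])), 1 / sum(v$outer$counts))
  }
  expect_error(stress_variant(plan, -100), "below 1")
})

test_that("cholesterol-asymmetric combination fixes the inner leaflet", {
  # outer-style leaflet at 33% CHOL, inner-style leaflets at lower CHOL
  o33 <- leaflet_plan(composition_counts(
    c(POPC = 0.55 * 0.67, PSM = 0.45 * 0.67, CHOL = 0.33), 66))
  i20 <- leaflet_plan(composition_counts(
    c(POPE = 0.5 * 0.8, POPC = 0.3 * 0.8, POPS = 0.2 * 0.8, CHOL = 0.2), 55))
  plan <- combine_asymchol(o33, i20)
  expect_identical(plan$inner$counts, i20$counts)
  # adjusted outer expected area within one mean APL of the inner's
  mean_apl <- sum((o33$counts / sum(o33$counts)) *
                    o33$apl[names(o33$counts)])
  expect_lte(abs(plan$outer$expected_area - i20$expected_area),
             mean_apl + 1e-9)
  # already matched: unchanged
  plan2 <- combine_asymchol(i20, i20)
  expect_identical(plan2$outer$counts, i20$counts)
})

test_that("two-compartment ion bookkeeping is neutral and Avogadro-exact", {
  outer <- leaflet_plan(c(POPC = 30L, PSM = 20L, CHOL = 10L))
  inner <- leaflet_plan(c(POPE = 28L, POPC = 16L, POPS = 6L, CHOL = 10L))
  plan <- assembly_plan(outer, inner, label = "D2")
  # 150 mM in a 100 nm^3 compartment: 9.03 -> 9 pairs
  phys <- plan_physiol_system(plan, 150, 150,
                              c(interior = 100, exterior = 100))
  expect_identical(unname(phys$ions$exterior[["anion"]]), 9L)
  expect_identical(unname(phys$ions$exterior[["cation"]]), 9L)
  # 12 PS across the two inner leaflets: 12 extra interior cations
  expect_identical(unname(phys$ions$interior[["cation"]]), 9L + 12L)
  expect_identical(unname(phys$ions$interior[["anion"]]), 9L)
  expect_equal(phys$net_charge, 0)
  # no salt, no charged lipids: zero ions
  plain <- assembly_plan(leaflet_plan(c(POPC = 50L)),
                         leaflet_plan(c(POPC = 50L)))
  phys0 <- plan_physiol_system(plain, 0, 0, c(interior = 50, exterior = 50))
  expect_identical(sum(unlist(phys0$ions)), 0L)
  expect_equal(phys0$net_charge, 0)
  expect_error(plan_physiol_system(plan, -1, 0, c(interior = 1, exterior = 1)),
               ">= 0")
})

test_that("realized structures match the planned counts exactly", {
  outer <- leaflet_plan(c(POPC = 26L, PSM = 22L, CHOL = 12L))
  inner <- leaflet_plan(c(POPE = 24L, POPC = 14L, POPS = 10L, CHOL = 12L))
  plan <- assembly_plan(outer, inner, label = "H20")
  rp <- realize_plan(plan, spec_defaults = list(seed = 51, water_count = 50L))
  expect_equal(n_frames(rp$trajectory), 1L)
  lf <- rp$manifest$leaflets
  expect_identical(lf$outer[sort(names(outer$counts))],
                   outer$counts[sort(names(outer$counts))])
  expect_identical(lf$inner[sort(names(inner$counts))],
                   inner$counts[sort(names(inner$counts))])
})

test_that("realized double-bilayer systems are mirror-consistent with ions", {
  outer <- leaflet_plan(c(POPC = 14L, PSM = 10L, CHOL = 6L))
  inner <- leaflet_plan(c(POPE = 12L, POPC = 8L, POPS = 4L, CHOL = 6L))
  plan <- assembly_plan(outer, inner, label = "D2")
  phys <- plan_physiol_system(plan, 150, 150, c(interior = 60, exterior = 60))
  rp <- realize_plan(phys, spec_defaults = list(seed = 52, water_count = 40L))
  at <- rp$trajectory$topology$atoms
  z <- rp$trajectory$coords[, 3L, 1L]
  # mirror symmetry: lipid z histogram is symmetric about 0
  lips <- at$species %in% c("POPC", "PSM", "POPE", "POPS", "CHOL")
  expect_equal(sum(z[lips] > 0), sum(z[lips] < 0))
  expect_equal(mean(z[lips]), 0, tolerance = 0.05)
  # total charge balances
  expect_equal(sum(at$charge), 0, tolerance = 1e-9)
  # both hydrophobic slabs are found as separated plateaus
  reg <- hydrophobic_bounds(recenter_frames(rp$trajectory), "tail_density")
  expect_length(reg, 2L)
  expect_identical(vapply(reg, `[[`, "", "label"), c("lower", "upper"))
})
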