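test_that("calibrated parameter sets reproduce the anchor productivities", {
  expect_equal(areal_productivity(growth_parameters("suspended")), 6.54,
               tolerance = 1e-6)
  expect_equal(areal_productivity(growth_parameters("biofilm")), 6.64,
               tolerance = 1e-6)
})

test_that("the calibration procedure reproduces the frozen constants", {
  cal <- calibrate_growth_parameters()
  expect_equal(cal$E_k, growth_parameters("suspended")$E_k, tolerance = 1e-9)
  expect_equal(cal$k_biofilm, growth_parameters("biofilm")$k, tolerance = 1e-9)
})

test_that("dark cultures respire: E_0 = 0 gives the pure respiration term", {
  p <- growth_parameters("suspended", E_0 = 0)
  expected <- -p$F_ratio * p$R_0 * p$C_c * p$gamma * p$t2
  expect_equal(areal_productivity(p), expected, tolerance = 1e-12)
  expect_lt(areal_productivity(p), 0)
})

test_that("a vanishing optical depth is rejected", {
  expect_error(areal_productivity(growth_parameters("suspended", k = 0)),
               "light gradient")
})

test_that("productivity is monotone in light, efficiency and respiration", {
  base <- growth_parameters("suspended")
  grid <- seq(0.2, 3, length.out = 10)
  p_e0 <- vapply(grid * base$E_0, function(v)
    areal_productivity(growth_parameters("suspended", E_0 = v)), 0)
  expect_true(all(diff(p_e0) > 0))
  alphas <- seq(0.02, 0.12, length.out = 8)
  p_a <- vapply(alphas, function(a)
    areal_productivity(growth_parameters("suspended", alpha = a)), 0)
  expect_true(all(diff(p_a) > 0))
  r0s <- seq(0.0005, 0.005, length.out = 8)
  p_r <- vapply(r0s, function(r)
    areal_productivity(growth_parameters("suspended", R_0 = r)), 0)
  expect_true(all(diff(p_r) < 0))
  ccs <- seq(0.2, 2, length.out = 8)
  p_c <- vapply(ccs, function(cc)
    areal_productivity(growth_parameters("suspended", C_c = cc)), 0)
  expect_true(all(diff(p_c) < 0))
})

test_that("the optically thin limit recovers the linearized light term", {
  p <- growth_parameters("suspended")
  thin <- function(kD) {
    exact <- log((p$E_k + p$E_0) / (p$E_k + p$E_0 * exp(-kD)))
    linear <- kD * p$E_0 / (p$E_k + p$E_0)
    abs(exact - linear) / linear
  }
  expect_lt(thin(1e-6), 1e-6)
  # first-order convergence of the relative error in kD
  expect_rel(thin(1e-3) / thin(1e-4), 10, 0.05)
})

test_that("farm sizing conserves the biomass demand", {
  sc <- builtin_scenario("state_of_the_art")
  d <- size_farm(sc, 52.4)
  expect_rel(d$land_area_m2, 52.4e6 / (6.64 * 500), 1e-12)
  expect_rel(d$harvest_rate_kg_sol, 104.8, 1e-12)
  expect_equal(d$land_area_m2 * sc$areal_productivity_g_m2_day *
                 sc$mission_length_sols / 1e6, 52.4, tolerance = 1e-12)
  expect_equal(d$illuminated_surface_area_m2, 1.84 * d$land_area_m2)
  expect_equal(size_farm(sc, 0)$land_area_m2, 0)
  sc2 <- sc; sc2$areal_productivity_g_m2_day <- 2 * 6.64
  expect_equal(size_farm(sc2, 52.4)$land_area_m2, d$land_area_m2 / 2)
})

test_that("cultivation water matches the design intensities", {
  susp <- size_farm(builtin_scenario("state_of_the_art_suspended"), 52.4)
  expect_rel(cultivation_water(susp), 6.64e5, 0.02)
  bio <- size_farm(builtin_scenario("state_of_the_art"), 52.4)
  expect_rel(cultivation_water(bio), 6.33e4, 0.02)
  expect_equal(cultivation_water(size_farm(builtin_scenario("state_of_the_art"),
                                           0)), 0)
})

test_that("cultivation power splits into mixing and pumping as designed", {
  susp <- size_farm(builtin_scenario("state_of_the_art_suspended"), 52.4)
  pw <- cultivation_power(susp, gravity_ratio = 0.38)
  expect_rel(pw$mixing_kw, 52 * 0.38 * susp$culture_volume_L / 1e6, 1e-12)
  expect_rel(pw$mixing_kw, 13.1, 0.02)
  # Earth gravity recovers the full mixing constant
  pw_earth <- cultivation_power(susp, gravity_ratio = 1)
  expect_rel(pw_earth$mixing_kw / pw$mixing_kw, 1 / 0.38, 1e-9)
  bio <- size_farm(builtin_scenario("state_of_the_art"), 52.4)
  pwb <- cultivation_power(bio)
  expect_equal(pwb$mixing_kw, 0)
  expect_rel(pwb$total_kw, 0.038 * bio$substrate_area_m2 / 1000, 1e-12)
  expect_rel(pwb$total_kw, 1.1, 0.05)
})

test_that("nutrient masses close against the biomass elemental composition", {
  nut <- nutrient_requirements(52.4, excess = 0.20)
  expect_rel(nut$dap_t, 0.75, 0.02)
  expect_rel(nut$ammonia_t, 1.20, 0.02)
  z <- nutrient_requirements(0)
  expect_equal(z$dap_t + z$ammonia_t + z$trace_media_t, 0)
  # shipped N and P exceed demand by exactly the excess fraction
  mol_c <- 52.4e6 / biomass_formula_mass(per_carbon = TRUE)
  expect_equal(nut$nitrogen_mol, 0.029 * mol_c * 1.2, tolerance = 1e-12)
  expect_equal(nut$phosphorus_mol, 0.002 * mol_c * 1.2, tolerance = 1e-12)
  # all P arrives as DAP, the nitrogen balance closes through ammonia
  dap_mol <- nut$dap_t * 1e6 / 132.056
  nh3_mol <- nut$ammonia_t * 1e6 / 17.031
  expect_equal(dap_mol, nut$phosphorus_mol, tolerance = 1e-9)
  expect_equal(2 * dap_mol + nh3_mol, nut$nitrogen_mol, tolerance = 1e-6)
})

test_that("cultivation payload reproduces the substrate-dominated breakdown", {
  sc_b <- builtin_scenario("state_of_the_art")
  bio <- size_farm(sc_b, 52.4)
  pb <- cultivation_payload(bio, sc_b, 52.4)
  expect_rel(pb$substrate_t / pb$total_t, 0.82, 0.04)
  sc_s <- builtin_scenario("state_of_the_art_suspended")
  susp <- size_farm(sc_s, 52.4)
  ps <- cultivation_payload(susp, sc_s, 52.4)
  expect_lt(pb$total_t, ps$total_t)  # biofilm cultivation is lighter
  # frame mass scales with gravity
  sc0 <- sc_b; sc0$gravity_ratio <- 0
  expect_equal(cultivation_payload(bio, sc0, 52.4)$frame_t, 0)
})
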