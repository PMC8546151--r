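test_that("streams carry non-negative compositions and mass flows", {
  s <- stream(100, biomass = 20, glucose = 5)
  mf <- species_mass_flow(s)
  expect_equal(unname(mf[["biomass"]]), 2)
  expect_equal(sum(mf), 100 * 1000 / 1000 / 1000 * 1000)  # 1 kg/L basis
  expect_error(stream(100, plutonium = 1), "unknown species")
  expect_error(stream(-1), "non-negative")
})

test_that("the concentrator conserves biomass and draws 5 kWh/m3", {
  # 105 kg biomass per sol harvested at 1 g/L
  feed <- stream(105000 / 24.66, biomass = 1)
  cc <- concentrator(feed, mode = "suspended")
  expect_equal(species_mass_flow(cc$out)[["biomass"]],
               species_mass_flow(feed)[["biomass"]], tolerance = 1e-12)
  expect_equal(cc$out$conc[["biomass"]], 20)
  expect_rel(cc$out$flow_L_h * 24.66, 5250, 1e-6)
  expect_rel(cc$metrics$power_kw, 5 * 105 / 24.66, 1e-9)   # ~21.3 kW
  expect_rel(cc$membrane_m2, (105000 - 5250) / 24.66 / 40, 1e-9)
  # water balance: permeate + retentate = feed
  expect_equal(cc$out$flow_L_h + cc$permeate$flow_L_h, feed$flow_L_h,
               tolerance = 1e-9)
})

test_that("biofilm mode bypasses the concentrator with zero metrics", {
  feed <- stream(212.9, biomass = 20)
  cc <- concentrator(feed, mode = "biofilm")
  expect_identical(cc$out, feed)
  expect_equal(cc$metrics$power_kw, 0)
  expect_equal(cc$metrics$payload_t, 0)
})

test_that("an already-concentrated feed needs no permeate or area", {
  feed <- stream(100, biomass = 20)
  cc <- concentrator(feed, mode = "suspended", target_conc_g_L = 20)
  expect_equal(cc$permeate$flow_L_h, 0)
  expect_equal(cc$membrane_m2, 0)
  expect_error(concentrator(feed, "suspended", target_conc_g_L = 10),
               "target concentration")
})

test_that("digestion yield interpolates and clamps on residence time", {
  expect_equal(digestion_yield(24), 0.30)
  expect_equal(digestion_yield(48), 0.45)
  expect_equal(digestion_yield(36), 0.375)
  expect_equal(digestion_yield(60), 0.45)
  expect_equal(digestion_yield(10), 0.30)
  expect_error(digestion_yield(0))
})

test_that("digester volume is linear in residence time and feed flow", {
  sc <- builtin_scenario("state_of_the_art")
  feed <- stream(212.9, biomass = 20)
  d48 <- digester(feed, sc, residence_h = 48)
  d24 <- digester(feed, sc, residence_h = 24)
  expect_equal(d48$working_volume_m3, 2 * d24$working_volume_m3)
  d2 <- digester(stream(2 * 212.9, biomass = 20), sc, residence_h = 48)
  expect_equal(d2$working_volume_m3, 2 * d48$working_volume_m3)
  expect_rel(d48$working_volume_m3, 10.2, 0.01)
  expect_rel(d48$metrics$power_kw, 1.5 * d48$working_volume_m3, 1e-12)
  # glucose released at the scenario yield
  expect_equal(d48$out$conc[["glucose"]], 20 * 0.45)
  z <- digester(stream(0, biomass = 20), sc)
  expect_equal(z$working_volume_m3, 0)
  expect_equal(z$metrics$power_kw, 0)
})

test_that("halving the digestion yield inflates the farm by the same factor", {
  # 24 h vs 48 h digestion: biomass demand scales inversely with yield
  demand <- function(res) 10 / (0.432 * digestion_yield(res))
  reduction <- 1 - demand(48) / demand(24)
  expect_rel(reduction, 0.34, 0.03)
})

test_that("the fermenter consumes all glucose at the design residence", {
  sc <- builtin_scenario("state_of_the_art")
  feed <- stream(208.59, glucose = 9, biomass = 11)
  fm <- fermenter(feed, sc)
  expect_equal(fm$residence_min, 72)
  expect_equal(fm$broth$conc[["glucose"]], 0)
  expect_equal(fm$broth$conc[["bdo"]], 9 * 0.432)
  # mission-scale conservation: broth BDO over 500 sols hits the 10 t target
  bdo_t <- species_mass_flow(fm$broth)[["bdo"]] * 500 * 24.66 / 1000
  glc_t <- species_mass_flow(feed)[["glucose"]] * 500 * 24.66 / 1000
  expect_rel(glc_t, 23.2, 0.005)
  expect_rel(bdo_t, 10, 0.005)
  expect_rel(fm$o2_demand_t, 12, 0.05)
  # feed-derived residence reproduces the concentration/rate quotient
  fm2 <- fermenter(feed, sc, basis = "from_feed")
  expect_rel(fm2$residence_min, 9 / (1.17 / 0.432) * 60, 1e-9)
})

test_that("stationary-phase productivity is a simple titer slope", {
  expect_rel(stationary_phase_productivity(0, 28, 24, 48), 1.17, 0.005)
  expect_equal(stationary_phase_productivity(5, 5, 0, 10), 0)
  expect_equal(stationary_phase_productivity(0, 28, 24, 48),
               stationary_phase_productivity(0, 56, 24, 72))
  expect_error(stationary_phase_productivity(0, 1, 10, 10))
})

test_that("vessel mass follows the 2.5 aspect geometry and material density", {
  m_steel <- vessel_mass(10, "steel")
  v <- 10 * 1.2
  r <- (v / (2.5 * pi))^(1 / 3)
  expect_equal(m_steel, 7 * pi * r^2 * 0.005 * 7.85, tolerance = 1e-12)
  expect_rel(vessel_mass(10, "HDPE") / m_steel, 0.97 / 7.85, 1e-9)
  expect_equal(vessel_mass(0), 0)
  expect_error(vessel_mass(1, "wood"), "unknown vessel material")
})

test_that("the backward sizing chain conserves mass for any scenario", {
  set.seed(3)
  for (i in 1:20) {
    sc <- scenario_config(
      cultivation_mode = sample(c("suspended", "biofilm"), 1),
      areal_productivity_g_m2_day = runif(1, 5, 15),
      digester_yield_g_g = runif(1, 0.3, 0.6),
      fermentation_yield_g_g = runif(1, 0.2, 0.51),
      bdo_target_t = runif(1, 5, 15))
    biomass <- sc$bdo_target_t / (sc$fermentation_yield_g_g *
                                    sc$digester_yield_g_g)
    recovered <- biomass * sc$digester_yield_g_g * sc$fermentation_yield_g_g
    expect_rel(recovered, sc$bdo_target_t, 0.005)
    d <- size_farm(sc, biomass)
    expect_rel(d$land_area_m2 * sc$areal_productivity_g_m2_day *
                 sc$mission_length_sols / 1e6, biomass, 1e-9)
  }
})
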