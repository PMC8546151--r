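# Physical constants, thermochemical tables and process design constants.
# All process constants are design-basis values; literature heats of combustion
# are higher heating values (liquid product water) at 298 K.

#' @keywords internal
.atomic_weights <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                     S = 32.06, P = 30.974)

# Mission / environment
.SOL_HOURS <- 24.66          # length of one Martian sol, h
.G_EARTH <- 9.81             # m/s^2 (Isp convention uses Earth g)
.GRAVITY_RATIO_MARS <- 0.38  # Mars surface gravity / Earth
.DHVAP_WATER_KJ_MOL <- 40.7  # heat of vaporization of water, kJ/mol

#' Built-in thermochemical table for candidate propellants
#'
#' Elemental formulas and standard (higher) heats of combustion, liquid product
#' water basis, for the fuels compared in the propellant design module.
#' RP-1 is approximated as n-dodecane. Values in kJ/mol.
#'
#' @return A data frame with columns `name`, `carbon`, `hydrogen`, `oxygen`,
#'   `heat_of_combustion_kj_mol`.
#' @export
propellant_constants <- function() {
  data.frame(
    name = c("methane", "methanol", "ethanol", "1,2-ethanediol",
             "1-propanol", "1,2-propanediol", "1,3-propanediol", "glycerol",
             "1-butanol", "1,3-butanediol", "2,3-butanediol", "RP-1"),
    carbon   = c(1, 1, 2, 2, 3, 3, 3, 3, 4, 4, 4, 12),
    hydrogen = c(4, 4, 6, 6, 8, 8, 8, 8, 10, 10, 10, 26),
    oxygen   = c(0, 1, 1, 2, 1, 2, 2, 3, 1, 2, 2, 0),
    heat_of_combustion_kj_mol = c(890.8, 726.1, 1366.8, 1189.2,
                                  2021.3, 1838.2, 1859.5, 1655.4,
                                  2670.9, 2501.5, 2461.0, 8086.5),
    stringsAsFactors = FALSE
  )
}

# Conservative specific impulse used as a mission sizing buffer, s
.ISP_CONSERVATIVE_BDO <- 383

# Mars Ascent Vehicle reference mission
.MAV_DELTA_V <- 5625      # m/s, to low Mars orbit
.MAV_EMPTY_MASS <- 8.542  # tons

# Material densities, t/m^3. Cotton is the fibre density of the woven
# biofilm substrate (fabric areal mass = thickness x fibre density).
.material_density <- c(steel = 7.85, aluminum = 2.70, HDPE = 0.97,
                       LDPE = 0.95, PVC = 1.38, cotton = 1.55)

# Cyanobacterial biomass elemental composition (per formula unit)
.biomass_composition <- c(C = 4.5, H = 8.2, N = 0.129, O = 2.219,
                          S = 0.006, P = 0.007)

#' Molar mass of the cyanobacterial biomass formula unit
#'
#' Computed from the elemental composition
#' C4.5 H8.2 N0.129 O2.219 S0.006 P0.007 and standard atomic weights
#' (about 100.0 g per formula unit, i.e. 22.23 g per mole of carbon).
#'
#' @param per_carbon If `TRUE`, return grams of biomass per mole of carbon.
#' @return Molar mass in g/mol.
#' @export
biomass_formula_mass <- function(per_carbon = FALSE) {
  m <- sum(.biomass_composition * .atomic_weights[names(.biomass_composition)])
  if (per_carbon) m / .biomass_composition[["C"]] else m
}

# Nutrient stoichiometry: moles of N and P required per mole of biomass carbon
.N_PER_MOL_C <- 0.029
.P_PER_MOL_C <- 0.002
.MW_DAP <- 132.056  # diammonium phosphate (NH4)2HPO4, g/mol
.MW_NH3 <- 17.031
.MW_O2 <- 31.998
.MW_GLUCOSE <- 180.156
.MW_BDO <- 90.122     # 2,3-butanediol C4H10O2
.MW_BUTANOL <- 74.122
.MW_WATER <- 18.015

# Trace-element growth medium, g/L of culture water
.trace_media_g_per_L <- c(NaCl = 1, CaCl2 = 0.03, K2SO4 = 1, MgSO4 = 0.008,
                          EDTA = 0.08, FeSO4 = 0.01, MnCl2 = 0.00023,
                          ZnSO4 = 0.00011, CuSO4 = 0.00003)

# Cultivation design basis
.F_RATIO <- 1.84                  # illuminated surface area / land area
.WATER_SUSPENDED_L_M2 <- 41.47    # L per m^2 land area
.WATER_BIOFILM_L_M2 <- 2.18      # L per m^2 substrate area
.SUSPENDED_CONC_G_L <- 1          # operating biomass concentration
.BIOFILM_HARVEST_G_L <- 20        # biofilm harvest slurry concentration
.SUBSTRATE_THICKNESS_M <- 3e-4    # PBR bag / biofilm substrate, 0.3 mm
.FRAME_STEEL_T_HA <- 78           # pilot-scale steel support structure
.BIOFILM_FRAME_FACTOR <- 0.11     # biofilm reactor mass relative to suspended

# Unit-operation power and sizing constants
.MIXING_W_M3_EARTH <- 52          # suspended culture mixing at Earth gravity
.PUMPING_KWH_M3 <- 0.058          # harvest pumping
.BIOFILM_PUMP_W_M2 <- 0.038       # biofilm nutrient resupply pumping
.CONCENTRATOR_KWH_M3 <- 5         # cross-flow filtration, per volume processed
.CONCENTRATOR_FLUX_L_M2_H <- 40   # long-term membrane flux
.CONCENTRATOR_MEMBRANE_M2 <- 155.61  # printed payload constant (see docs)
.VESSEL_MIXING_KW_M3 <- 1.5       # digester/fermenter/LLE impeller mixing
.VESSEL_EXCESS <- 0.20
.VESSEL_ASPECT <- 2.5             # height / radius
.VESSEL_WALL_M <- 0.005           # default wall thickness
.ENZYME_G_L <- 3                  # 1 g/L each of lysozyme, amylase, glucoamylase
.ENZYME_LIFE_SOLS <- 10
.FERMENT_O2_MOL_L_H <- 0.12       # fermenter oxygen uptake
.RO_FLUX_L_M2_H <- 25             # thin-film composite water flux
.RO_MEMBRANE_THICKNESS_M <- 2e-4
.MEMBRANE_DENSITY_T_M3 <- 1.24    # polymeric membrane material
.STORAGE_BDO_M3 <- 16
.STORAGE_O2_M3 <- 28
.STORAGE_WALL_M <- 0.006          # HDPE storage tanks

# DRA 5.0 "O2 only" chemical-ISRU comparison constants (fixed, never recomputed)
.DRA_PAYLOAD_T <- 7.5
.DRA_POWER_KW <- 26.08
.DRA_O2_T <- 22.98
.DRA_RESUPPLY_T <- 6.5
.LAUNCH_O2_T <- 19.64             # LOX for the 10 t conservative launch target

# Saturation vapour pressures at 25 C, kPa (pervaporation driving force)
.PSAT_25C_KPA <- c(water = 3.17, butanol = 0.86, bdo = 0.023)
# Latent heats at 25 C, kJ/kg
.DHVAP_KJ_KG <- c(water = 2442, butanol = 582, bdo = 800)
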