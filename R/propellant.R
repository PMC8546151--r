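# Propellant design: combustion stoichiometry, heating values, theoretical
# specific impulse and ideal-rocket-equation mission sizing for CxHyOz fuels.
#
# The specific impulse is the simplified kinetic-energy bound: complete
# combustion, all chemical energy converted to exhaust kinetic energy,
#   Isp = sqrt(2 (dH - n_H2O dHvap) / m_ex) / g
# with dH the higher heating value (liquid product water), the vaporization
# of product water subtracted explicitly, and m_ex the exhaust mass produced
# per mole of fuel (kg/mol). No nozzle, chamber or dissociation modeling.

#' Define a propellant
#'
#' @param name Fuel name; if it matches an entry of [propellant_constants()],
#'   the remaining arguments default to the tabulated values.
#' @param carbon,hydrogen,oxygen Atom counts of the CxHyOz formula.
#' @param heat_of_combustion_kj_mol Standard heat of combustion (higher
#'   heating value, liquid water product), kJ/mol.
#' @param molar_mass_g_mol Optional; computed from the formula when `NULL`,
#'   and checked against the formula (0.1 g/mol) when supplied.
#' @return An object of class `propellant_spec`.
#' @examples
#' propellant("2,3-butanediol")
#' propellant("dimethyl ether", carbon = 2, hydrogen = 6, oxygen = 1,
#'            heat_of_combustion_kj_mol = 1460.4)
#' @export
propellant <- function(name, carbon = NULL, hydrogen = NULL, oxygen = NULL,
                       heat_of_combustion_kj_mol = NULL,
                       molar_mass_g_mol = NULL) {
  tab <- propellant_constants()
  if (is.null(carbon)) {
    row <- tab[tab$name == name, ]
    if (nrow(row) != 1)
      stop("unknown propellant '", name,
           "'; supply the formula and heat of combustion explicitly")
    carbon <- row$carbon; hydrogen <- row$hydrogen; oxygen <- row$oxygen
    heat_of_combustion_kj_mol <- row$heat_of_combustion_kj_mol
  }
  stopifnot(carbon >= 0, hydrogen >= 1, oxygen >= 0,
            heat_of_combustion_kj_mol > 0)
  mw <- carbon * .atomic_weights[["C"]] + hydrogen * .atomic_weights[["H"]] +
    oxygen * .atomic_weights[["O"]]
  if (!is.null(molar_mass_g_mol) && abs(molar_mass_g_mol - mw) > 0.1)
    stop(sprintf("molar mass %.3f inconsistent with formula (%.3f g/mol)",
                 molar_mass_g_mol, mw))
  structure(list(name = name, carbon = carbon, hydrogen = hydrogen,
                 oxygen = oxygen, molar_mass_g_mol = mw,
                 heat_of_combustion_kj_mol = heat_of_combustion_kj_mol),
            class = "propellant_spec")
}

#' Complete-combustion stoichiometry of a CxHyOz fuel
#'
#' Balances CxHyOz + (x + y/4 - z/2) O2 -> x CO2 + (y/2) H2O and derives the
#' oxygen-to-propellant mass ratio, the exhaust mass per mole of fuel, and the
#' lower heating value.
#'
#' @param spec A `propellant_spec`.
#' @return A list of class `combustion_result` with `n_O2`, `n_CO2`, `n_H2O`
#'   (mol per mol fuel), `O_P_ratio` (g O2 / g fuel), `m_ex_kg_mol` (kg exhaust
#'   per mol fuel) and `LHV_MJ_kg`.
#' @examples
#' combustion(propellant("methane"))$O_P_ratio   # ~4
#' combustion(propellant("methanol"))$O_P_ratio  # ~1.5
#' @export
combustion <- function(spec) {
  stopifnot(inherits(spec, "propellant_spec"))
  n_O2 <- spec$carbon + spec$hydrogen / 4 - spec$oxygen / 2
  if (n_O2 < 0)
    stop("over-oxygenated formula: negative O2 requirement")
  n_CO2 <- spec$carbon
  n_H2O <- spec$hydrogen / 2
  m_ex_kg_mol <- (spec$molar_mass_g_mol + n_O2 * .MW_O2) / 1000
  lhv_kj_mol <- spec$heat_of_combustion_kj_mol - n_H2O * .DHVAP_WATER_KJ_MOL
  structure(list(
    n_O2 = n_O2, n_CO2 = n_CO2, n_H2O = n_H2O,
    O_P_ratio = n_O2 * .MW_O2 / spec$molar_mass_g_mol,
    m_ex_kg_mol = m_ex_kg_mol,
    LHV_MJ_kg = lhv_kj_mol / spec$molar_mass_g_mol
  ), class = "combustion_result")
}

#' Mission specification for rocket-equation sizing
#'
#' @param delta_v_m_s Required change in velocity (default 5625 m/s, surface
#'   to low Mars orbit).
#' @param empty_mass_t Dry mass of the ascent vehicle, tons (default 8.542).
#' @param g_m_s2 Gravitational acceleration used in the Isp convention
#'   (Earth standard, 9.81 m/s^2).
#' @return An object of class `mission_spec`.
#' @export
mission_spec <- function(delta_v_m_s = .MAV_DELTA_V,
                         empty_mass_t = .MAV_EMPTY_MASS,
                         g_m_s2 = .G_EARTH) {
  stopifnot(delta_v_m_s >= 0, empty_mass_t > 0, g_m_s2 > 0)
  structure(list(delta_v_m_s = delta_v_m_s, empty_mass_t = empty_mass_t,
                 g_m_s2 = g_m_s2), class = "mission_spec")
}

#' Theoretical specific impulse
#'
#' Kinetic-energy upper bound on specific impulse, in seconds: the net heat of
#' combustion (heating value minus vaporization of the product water) fully
#' converted to exhaust kinetic energy, divided by Earth standard gravity.
#'
#' @param spec A `propellant_spec`.
#' @param mission A `mission_spec` (supplies the g convention).
#' @return Specific impulse in seconds.
#' @examples
#' theoretical_isp(propellant("2,3-butanediol"))  # ~420 s
#' theoretical_isp(propellant("methane"))         # ~459 s
#' @export
theoretical_isp <- function(spec, mission = mission_spec()) {
  comb <- combustion(spec)
  net_kj <- spec$heat_of_combustion_kj_mol - comb$n_H2O * .DHVAP_WATER_KJ_MOL
  if (net_kj <= 0)
    stop("no net energy: heat of combustion does not exceed product-water ",
         "vaporization")
  sqrt(2 * net_kj * 1000 / comb$m_ex_kg_mol) / mission$g_m_s2
}

#' Propellant mass required for a mission
#'
#' Ideal rocket equation dv = Isp g ln(m_f / m_e): the full mass
#' m_f = m_e exp(dv / (Isp g)), total propellant m_f - m_e, split between fuel
#' and liquid oxygen by the stoichiometric oxygen-to-propellant mass ratio.
#'
#' @param mission A `mission_spec`.
#' @param isp Specific impulse in seconds. Use [theoretical_isp()] or the
#'   conservative buffer value (see `conservative`).
#' @param comb A `combustion_result` (supplies the O/P ratio).
#' @param conservative If `TRUE`, ignore `isp` and use the conservative
#'   2,3-BDO buffer value of 383 s.
#' @return A list with `fuel_t`, `lox_t` and `total_t` (tons).
#' @examples
#' p <- propellant("2,3-butanediol")
#' propellant_for_mission(mission_spec(), theoretical_isp(p), combustion(p))
#' @export
propellant_for_mission <- function(mission, isp, comb, conservative = FALSE) {
  stopifnot(inherits(mission, "mission_spec"),
            inherits(comb, "combustion_result"))
  if (conservative) isp <- .ISP_CONSERVATIVE_BDO
  stopifnot(isp > 0)
  m_f <- mission$empty_mass_t *
    exp(mission$delta_v_m_s / (isp * mission$g_m_s2))
  total <- m_f - mission$empty_mass_t
  fuel <- total / (1 + comb$O_P_ratio)
  list(fuel_t = fuel, lox_t = fuel * comb$O_P_ratio, total_t = total)
}

#' Propellant comparison table
#'
#' O/P ratio, lower heating value, theoretical specific impulse and
#' rocket-equation fuel/LOX requirement for every fuel in the built-in
#' thermochemical table.
#'
#' @param mission A `mission_spec`.
#' @return A data frame, one row per fuel.
#' @export
propellant_table <- function(mission = mission_spec()) {
  tab <- propellant_constants()
  rows <- lapply(tab$name, function(nm) {
    p <- propellant(nm)
    cb <- combustion(p)
    isp <- theoretical_isp(p, mission)
    sz <- propellant_for_mission(mission, isp, cb)
    data.frame(name = nm,
               formula = sprintf("C%gH%gO%g", p$carbon, p$hydrogen, p$oxygen),
               molar_mass_g_mol = p$molar_mass_g_mol,
               O_P_ratio = cb$O_P_ratio, LHV_MJ_kg = cb$LHV_MJ_kg,
               Isp_s = isp, fuel_t = sz$fuel_t, lox_t = sz$lox_t)
  })
  do.call(rbind, rows)
}
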