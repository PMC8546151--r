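# Mission-level aggregation: run the whole flowsheet for a scenario, sum the
# per-unit water/power/payload metrics, close the oxygen ledger, and compare
# against the DRA 5.0 "O2 only" chemical-ISRU constants.

#' Oxygen ledger
#'
#' Photosynthesis evolves one mole of O2 per mole of CO2 fixed into biomass;
#' the ledger nets off the fermenter's O2 consumption and the launch LOX
#' requirement.
#'
#' @param biomass_t Cyanobacterial biomass produced over the mission, tons.
#' @param fermenter_o2_t Fermenter O2 consumption over the mission, tons.
#' @param launch_o2_t LOX required for the ascent, tons.
#' @return A list of class `o2_ledger` with `gross_t`, `net_t` (after the
#'   fermenter), and `excess_t` (after launch). Negative excess is an
#'   infeasibility error.
#' @examples
#' o2_ledger(52.4, 12, 19.64)
#' @export
o2_ledger <- function(biomass_t, fermenter_o2_t, launch_o2_t = .LAUNCH_O2_T) {
  stopifnot(biomass_t >= 0, fermenter_o2_t >= 0, launch_o2_t >= 0)
  mol_c <- biomass_t * 1e6 / biomass_formula_mass(per_carbon = TRUE)
  gross <- mol_c * .MW_O2 / 1e6
  net <- gross - fermenter_o2_t
  excess <- net - launch_o2_t
  if (excess < 0)
    stop(sprintf("infeasible oxygen balance: %.2f t short", -excess))
  structure(list(gross_t = gross, fermenter_t = fermenter_o2_t,
                 launch_t = launch_o2_t, net_t = net, excess_t = excess),
            class = "o2_ledger")
}

# Storage tanks for the product and the launch oxygen: fixed 16 and 28 m^3
# HDPE vessels with 6 mm walls, independent of the scenario vessel material.
.storage_payload_t <- function() {
  vessel_mass(.STORAGE_BDO_M3, "HDPE", wall_m = .STORAGE_WALL_M, excess = 0) +
    vessel_mass(.STORAGE_O2_M3, "HDPE", wall_m = .STORAGE_WALL_M, excess = 0)
}

#' Run the full bio-ISRU flowsheet for a scenario
#'
#' Sizes the process backwards from the 2,3-BDO target (target / fermentation
#' yield = glucose; glucose / digester yield = biomass), sizes the farm,
#' chains cultivation, concentration, digestion, fermentation and the
#' converged separation train, and aggregates per-unit water, power and
#' payload metrics with the oxygen ledger.
#'
#' @param scenario A `scenario_config`.
#' @param separation If `FALSE`, skip the converged separation train (its
#'   stream results) and use zero separation metrics; useful for quick sweeps.
#' @param ... Passed to [solve_recycle()].
#' @return An object of class `process_report`: `units` (data frame of unit x
#'   {water_L, power_kw, payload_t}), `totals`, `o2` ledger, `consumables_t`,
#'   `resupply_t`, `streams`, `comparison` versus the DRA 5.0 constants
#'   (ratios recomputed at access time, never stored inputs), and the
#'   intermediate design objects.
#' @examples
#' \donttest{
#' rep <- aggregate_process(builtin_scenario("state_of_the_art"))
#' rep$totals
#' }
#' @export
aggregate_process <- function(scenario, separation = TRUE, ...) {
  validate_scenario(scenario)
  bdo_t <- scenario$bdo_target_t
  glucose_t <- bdo_t / scenario$fermentation_yield_g_g
  biomass_t <- glucose_t / scenario$digester_yield_g_g

  design <- size_farm(scenario, biomass_t)
  cult_water <- cultivation_water(design)
  cult_power <- cultivation_power(design, scenario$gravity_ratio)
  cult_pay <- cultivation_payload(design, scenario, biomass_t)
  cult <- .unit_metrics(water_L = cult_water,
                        power_kw = cult_power$total_kw,
                        payload_t = cult_pay$total_t)

  # harvest stream at the operating concentration
  if (scenario$cultivation_mode == "suspended") {
    flow <- design$harvest_rate_kg_sol * 1000 /
      design$operating_concentration / .SOL_HOURS
    harvest <- stream(flow, biomass = design$operating_concentration)
  } else {
    flow <- design$harvest_rate_kg_sol * 1000 /
      .BIOFILM_HARVEST_G_L / .SOL_HOURS
    harvest <- stream(flow, biomass = .BIOFILM_HARVEST_G_L)
  }
  conc <- concentrator(harvest, mode = scenario$cultivation_mode,
                       vessel_material = scenario$vessel_material)
  dig <- digester(conc$out, scenario)
  ferm <- fermenter(dig$out, scenario)

  if (separation) {
    sep <- solve_recycle(ferm$broth, scenario, ...)
    sep_units <- sep$metrics
  } else {
    sep <- NULL
    sep_units <- list(lle = .unit_metrics(), pervaporation = .unit_metrics(),
                      water_recycle = .unit_metrics())
  }
  storage <- .unit_metrics(payload_t = .storage_payload_t())

  units <- list(cultivation = cult, concentrator = conc$metrics,
                digester = dig$metrics, fermenter = ferm$metrics,
                lle = sep_units$lle, pervaporation = sep_units$pervaporation,
                water_recycle = sep_units$water_recycle, storage = storage)
  tab <- data.frame(
    unit = names(units),
    water_L = vapply(units, `[[`, 0, "water_L"),
    power_kw = vapply(units, `[[`, 0, "power_kw"),
    payload_t = vapply(units, `[[`, 0, "payload_t"),
    row.names = NULL
  )
  totals <- c(water_L = sum(tab$water_L), power_kw = sum(tab$power_kw),
              payload_t = sum(tab$payload_t))

  consum <- c()
  for (u in units) consum <- c(consum, u$consumables_t)
  substrate_t <- if (scenario$cultivation_mode == "biofilm")
    cult_pay$substrate_t else 0

  launch_o2 <- bdo_t * combustion(propellant("2,3-butanediol"))$O_P_ratio
  o2 <- o2_ledger(biomass_t, ferm$o2_demand_t, launch_o2)

  structure(list(
    scenario = scenario, biomass_t = biomass_t, glucose_t = glucose_t,
    units = tab, totals = totals, o2 = o2,
    consumables_t = consum,
    resupply_components_t = c(substrate = substrate_t,
                              enzymes = unname(consum["enzymes"])),
    design = design, cultivation_payload = cult_pay,
    digester_volume_m3 = dig$working_volume_m3,
    fermenter_volume_m3 = ferm$working_volume_m3,
    separation = sep
  ), class = "process_report")
}

#' DRA 5.0 comparison block
#'
#' Ratios of the report totals to the fixed DRA 5.0 "O2 only" constants
#' (7.5 t payload, 26.08 kW power, 22.98 t O2). Recomputed from the report on
#' every call; the constants are never recomputed.
#'
#' @param report A `process_report`.
#' @return A list with the DRA constants and the payload/power ratios.
#' @export
dra_comparison <- function(report) {
  stopifnot(inherits(report, "process_report"))
  list(dra_payload_t = .DRA_PAYLOAD_T, dra_power_kw = .DRA_POWER_KW,
       dra_o2_t = .DRA_O2_T,
       payload_ratio = unname(report$totals["payload_t"]) / .DRA_PAYLOAD_T,
       power_ratio = unname(report$totals["power_kw"]) / .DRA_POWER_KW)
}

#' Swap materials of construction in a report
#'
#' Recomputes the report with a different biofilm substrate and/or vessel
#' material. Only material-dependent payload terms change; all flows and
#' power draws are invariant to the swap (asserted).
#'
#' @param report A `process_report`.
#' @param substrate_material New growth-substrate material (or `NULL` to keep).
#' @param vessel_material New vessel material (or `NULL` to keep).
#' @return A new `process_report`.
#' @export
materials_swap <- function(report, substrate_material = NULL,
                           vessel_material = NULL) {
  stopifnot(inherits(report, "process_report"))
  sc <- report$scenario
  if (!is.null(substrate_material)) sc$substrate_material <- substrate_material
  if (!is.null(vessel_material)) sc$vessel_material <- vessel_material
  validate_scenario(sc)
  out <- aggregate_process(sc, separation = !is.null(report$separation))
  stopifnot(isTRUE(all.equal(out$totals[["water_L"]],
                             report$totals[["water_L"]])),
            isTRUE(all.equal(out$totals[["power_kw"]],
                             report$totals[["power_kw"]], tolerance = 1e-6)))
  out
}

#' Resupply payload for a follow-on mission
#'
#' Durable equipment is reused across missions; only consumables with a
#' sub-mission lifetime return on the manifest: the biofilm growth substrate
#' (1-2 year lifetime) and the digestion enzymes (shipped per mission).
#' Nutrients and butanol are assumed recovered.
#'
#' @param report A `process_report`.
#' @return Resupply mass in tons.
#' @export
resupply_mass <- function(report) {
  stopifnot(inherits(report, "process_report"))
  sum(report$resupply_components_t, na.rm = TRUE)
}

#' Serialize a process report
#'
#' Writes `units.csv` (unit x metric table) and `report.json` (totals, oxygen
#' ledger, consumables, comparison block) to a directory.
#'
#' @param report A `process_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "process_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$units, file.path(dir, "units.csv"),
                   row.names = FALSE)
  summary <- list(
    scenario = unclass(report$scenario),
    biomass_t = report$biomass_t, glucose_t = report$glucose_t,
    totals = as.list(report$totals), o2 = unclass(report$o2),
    consumables_t = as.list(report$consumables_t),
    resupply_t = resupply_mass(report),
    comparison = dra_comparison(report)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.process_report <- function(x, ...) {
  cat(sprintf("<process_report> %s / %s, %.3g t 2,3-BDO over %g sols\n",
              x$scenario$cultivation_mode, x$scenario$substrate_material,
              x$scenario$bdo_target_t, x$scenario$mission_length_sols))
  cat(sprintf("  biomass %.4g t, glucose %.4g t\n", x$biomass_t, x$glucose_t))
  print(x$units, digits = 4)
  cat(sprintf("  totals: %.4g L water, %.4g kW, %.4g t payload\n",
              x$totals["water_L"], x$totals["power_kw"],
              x$totals["payload_t"]))
  cat(sprintf("  O2: gross %.4g t, net %.4g t, excess %.4g t\n",
              x$o2$gross_t, x$o2$net_t, x$o2$excess_t))
  invisible(x)
}
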