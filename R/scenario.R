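# Scenario definitions: the full parameter set that drives every downstream
# stage of the process model, plus the seeded sweep generator used for the
# optimization grids.

.scenario_fields <- c(
  "cultivation_mode", "areal_productivity_g_m2_day", "digester_yield_g_g",
  "digester_residence_h", "fermentation_yield_g_g",
  "fermentation_productivity_g_l_h", "bdo_target_t", "mission_length_sols",
  "substrate_material", "vessel_material", "nutrient_excess_fraction",
  "gravity_ratio"
)

.FERMENTATION_YIELD_MAX <- 0.538  # FBA theoretical maximum for 2,3-BDO, g/g

#' Construct and validate a scenario configuration
#'
#' A scenario bundles every tunable parameter of the bio-ISRU process model:
#' cultivation mode and productivity, digestion and fermentation yields,
#' the mission production target, and the materials of construction.
#'
#' @param cultivation_mode `"suspended"` or `"biofilm"`.
#' @param areal_productivity_g_m2_day Cyanobacterial biomass productivity per
#'   m^2 of land per sol.
#' @param digester_yield_g_g Glucose released per gram of biomass (0, 1].
#' @param digester_residence_h Enzymatic digester residence time, hours.
#' @param fermentation_yield_g_g 2,3-BDO per gram of glucose; bounded above by
#'   the theoretical maximum 0.538 g/g.
#' @param fermentation_productivity_g_l_h Steady-state 2,3-BDO volumetric
#'   productivity.
#' @param bdo_target_t Mission production target, tons of 2,3-BDO.
#' @param mission_length_sols Mission duration in sols (1 sol = 24.66 h; all
#'   "per day" rates in the model are per sol).
#' @param substrate_material Growth substrate material, `"cotton"` or `"LDPE"`.
#' @param vessel_material Vessel material, `"steel"`, `"aluminum"` or `"HDPE"`.
#' @param nutrient_excess_fraction Fractional nutrient over-supply (default 20%).
#' @param gravity_ratio Local gravity relative to Earth (0.38 for Mars).
#' @return An object of class `scenario_config` (a validated named list).
#' @examples
#' sc <- scenario_config(cultivation_mode = "biofilm",
#'                       areal_productivity_g_m2_day = 6.64)
#' sc$digester_yield_g_g
#' @export
scenario_config <- function(cultivation_mode = c("biofilm", "suspended"),
                            areal_productivity_g_m2_day = 6.64,
                            digester_yield_g_g = 0.45,
                            digester_residence_h = 48,
                            fermentation_yield_g_g = 0.432,
                            fermentation_productivity_g_l_h = 1.17,
                            bdo_target_t = 10,
                            mission_length_sols = 500,
                            substrate_material = c("cotton", "LDPE"),
                            vessel_material = c("steel", "aluminum", "HDPE"),
                            nutrient_excess_fraction = 0.20,
                            gravity_ratio = .GRAVITY_RATIO_MARS) {
  sc <- list(
    cultivation_mode = match.arg(cultivation_mode),
    areal_productivity_g_m2_day = areal_productivity_g_m2_day,
    digester_yield_g_g = digester_yield_g_g,
    digester_residence_h = digester_residence_h,
    fermentation_yield_g_g = fermentation_yield_g_g,
    fermentation_productivity_g_l_h = fermentation_productivity_g_l_h,
    bdo_target_t = bdo_target_t,
    mission_length_sols = mission_length_sols,
    substrate_material = match.arg(substrate_material),
    vessel_material = match.arg(vessel_material),
    nutrient_excess_fraction = nutrient_excess_fraction,
    gravity_ratio = gravity_ratio
  )
  class(sc) <- "scenario_config"
  validate_scenario(sc)
}

#' Validate a scenario configuration
#'
#' Checks the invariants every downstream module relies on: strictly positive
#' rates and yields, digester yield in (0, 1], fermentation yield below the
#' theoretical maximum, recognized materials.
#'
#' @param sc A `scenario_config`.
#' @return `sc`, invisibly unchanged, or an error.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario_config"))
  missing <- setdiff(.scenario_fields, names(sc))
  if (length(missing))
    stop("scenario is missing fields: ", paste(missing, collapse = ", "))
  num <- c("areal_productivity_g_m2_day", "digester_yield_g_g",
           "digester_residence_h", "fermentation_yield_g_g",
           "fermentation_productivity_g_l_h", "bdo_target_t",
           "mission_length_sols", "nutrient_excess_fraction", "gravity_ratio")
  for (f in num) {
    v <- sc[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("scenario field '", f, "' must be a finite number")
  }
  if (sc$areal_productivity_g_m2_day <= 0) stop("areal productivity must be > 0")
  if (sc$digester_yield_g_g <= 0 || sc$digester_yield_g_g > 1)
    stop("digester yield must be in (0, 1]")
  if (sc$digester_residence_h <= 0) stop("digester residence must be > 0")
  if (sc$fermentation_yield_g_g <= 0 ||
      sc$fermentation_yield_g_g > .FERMENTATION_YIELD_MAX)
    stop("fermentation yield must be in (0, ", .FERMENTATION_YIELD_MAX,
         "] g/g (theoretical maximum for 2,3-BDO)")
  if (sc$fermentation_productivity_g_l_h <= 0)
    stop("fermentation productivity must be > 0")
  if (sc$bdo_target_t <= 0) stop("bdo target must be > 0")
  if (sc$mission_length_sols <= 0) stop("mission length must be > 0")
  if (sc$nutrient_excess_fraction < 0) stop("nutrient excess must be >= 0")
  if (sc$gravity_ratio < 0) stop("gravity ratio must be >= 0")
  if (!sc$cultivation_mode %in% c("suspended", "biofilm"))
    stop("unknown cultivation mode: ", sc$cultivation_mode)
  if (!sc$substrate_material %in% c("cotton", "LDPE"))
    stop("unknown substrate material: ", sc$substrate_material)
  if (!sc$vessel_material %in% c("steel", "aluminum", "HDPE"))
    stop("unknown vessel material: ", sc$vessel_material)
  invisible(sc)
}

#' Built-in reference scenarios
#'
#' `"state_of_the_art"` is the biofilm process at currently demonstrated
#' biology (6.64 g/m^2/day, 45 wt% digestion at 48 h, 0.432 g/g fermentation
#' yield, cotton substrate, steel vessels). `"optimized"` applies the
#' model-guided improvements (13.28 g/m^2/day, 60 wt% digestion, 0.51 g/g
#' yield, LDPE substrate, HDPE vessels). `"state_of_the_art_suspended"` is the
#' suspended-growth variant (6.54 g/m^2/day) used for the cultivation-mode
#' comparison. All target 10 t of 2,3-BDO over 500 sols.
#'
#' @param name One of `"state_of_the_art"`, `"optimized"`,
#'   `"state_of_the_art_suspended"`.
#' @return A `scenario_config`.
#' @examples
#' builtin_scenario("optimized")$fermentation_yield_g_g
#' @export
builtin_scenario <- function(name = c("state_of_the_art", "optimized",
                                      "state_of_the_art_suspended")) {
  name <- match.arg(name)
  switch(name,
    state_of_the_art = scenario_config(
      cultivation_mode = "biofilm", areal_productivity_g_m2_day = 6.64,
      digester_yield_g_g = 0.45, digester_residence_h = 48,
      fermentation_yield_g_g = 0.432, fermentation_productivity_g_l_h = 1.17,
      substrate_material = "cotton", vessel_material = "steel"),
    state_of_the_art_suspended = scenario_config(
      cultivation_mode = "suspended", areal_productivity_g_m2_day = 6.54,
      digester_yield_g_g = 0.45, digester_residence_h = 48,
      fermentation_yield_g_g = 0.432, fermentation_productivity_g_l_h = 1.17,
      substrate_material = "LDPE", vessel_material = "steel"),
    optimized = scenario_config(
      cultivation_mode = "biofilm", areal_productivity_g_m2_day = 13.28,
      digester_yield_g_g = 0.60, digester_residence_h = 48,
      fermentation_yield_g_g = 0.51, fermentation_productivity_g_l_h = 1.17,
      substrate_material = "LDPE", vessel_material = "HDPE")
  )
}

# Validity ranges for sweepable numeric parameters
.sweep_ranges <- list(
  areal_productivity_g_m2_day = c(1e-6, 30),
  digester_yield_g_g = c(1e-6, 1),
  digester_residence_h = c(1e-6, 168),
  fermentation_yield_g_g = c(1e-6, .FERMENTATION_YIELD_MAX),
  fermentation_productivity_g_l_h = c(1e-6, 10),
  bdo_target_t = c(1e-6, 100),
  nutrient_excess_fraction = c(0, 1),
  gravity_ratio = c(0, 1)
)

#' Sweep specification
#'
#' Either an explicit grid of values or `n` seeded uniform draws between
#' `lower` and `upper` for one scenario parameter.
#'
#' @param parameter Name of the numeric scenario field to sweep.
#' @param grid Explicit values (mutually exclusive with `lower`/`upper`).
#' @param lower,upper Bounds for random draws.
#' @param n Number of random draws.
#' @param seed Integer seed; the same seed always reproduces the same draws.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, grid = NULL, lower = NULL, upper = NULL,
                       n = NULL, seed = 1L) {
  if (!parameter %in% names(.sweep_ranges))
    stop("parameter '", parameter, "' is not sweepable")
  if (is.null(grid) == is.null(lower))
    stop("provide either a grid or lower/upper bounds, not both")
  rng <- .sweep_ranges[[parameter]]
  if (!is.null(grid)) {
    if (length(grid) && (any(grid < rng[1]) || any(grid > rng[2])))
      stop("grid values outside the validity range [", rng[1], ", ", rng[2],
           "] of '", parameter, "'")
  } else {
    stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper,
              is.numeric(n), n >= 1)
    if (lower < rng[1] || upper > rng[2])
      stop("bounds outside the validity range of '", parameter, "'")
  }
  structure(list(parameter = parameter, grid = grid, lower = lower,
                 upper = upper, n = if (is.null(n)) NULL else as.integer(n),
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Generate a parameter sweep over scenarios
#'
#' Emits one validated scenario per grid point (or per seeded draw), differing
#' from `base` only in the swept parameter. Deterministic for a fixed seed.
#'
#' @param base A `scenario_config` to perturb.
#' @param spec A `sweep_spec`.
#' @return A list of `scenario_config` objects.
#' @examples
#' sw <- generate_sweep(builtin_scenario("state_of_the_art"),
#'                      sweep_spec("areal_productivity_g_m2_day",
#'                                 grid = c(5, 10, 15)))
#' vapply(sw, `[[`, 1, "areal_productivity_g_m2_day")
#' @export
generate_sweep <- function(base, spec) {
  validate_scenario(base)
  stopifnot(inherits(spec, "sweep_spec"))
  values <- if (!is.null(spec$grid)) {
    spec$grid
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    stats::runif(spec$n, spec$lower, spec$upper)
  }
  lapply(values, function(v) {
    sc <- base
    sc[[spec$parameter]] <- v
    validate_scenario(sc)
    sc
  })
}

#' Write a scenario to a flat key/value text file
#'
#' One `key = value` pair per line, keys carrying their units; the format
#' round-trips byte-identically through [read_scenario()].
#'
#' @param sc A `scenario_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  validate_scenario(sc)
  fmt <- function(v) if (is.character(v)) v else sprintf("%.15g", v)
  lines <- sprintf("%s = %s", .scenario_fields,
                   vapply(sc[.scenario_fields], fmt, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scenario from a flat key/value text file
#'
#' Unknown keys are an error (fail-fast); missing keys fail validation.
#'
#' @param path File written by [write_scenario()] or hand-edited in the same
#'   format.
#' @return A validated `scenario_config`.
#' @export
read_scenario <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(m) != 3
  if (any(bad)) stop("malformed scenario line: ", lines[bad][1])
  keys <- trimws(vapply(m, `[`, "", 2))
  vals <- trimws(vapply(m, `[`, "", 3))
  unknown <- setdiff(keys, .scenario_fields)
  if (length(unknown))
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "))
  sc <- stats::setNames(as.list(vals), keys)
  chr <- c("cultivation_mode", "substrate_material", "vessel_material")
  for (f in setdiff(keys, chr)) sc[[f]] <- as.numeric(sc[[f]])
  sc <- sc[.scenario_fields]
  class(sc) <- "scenario_config"
  validate_scenario(sc)
  sc
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  for (f in .scenario_fields) cat(sprintf("  %-34s %s\n", f, x[[f]]))
  invisible(x)
}
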