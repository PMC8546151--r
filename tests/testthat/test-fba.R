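toy_model <- function() {
  read_bigg_json(system.file("extdata", "toy_model_synthetic.json",
                             package = "bioisru"))
}

# product pathway grafted onto the synthetic base network:
# B (C3H4O3) + 3 H2 -> P (C3H8O2) + H2O, then transport and export
toy_product_patch <- function() {
  pathway_patch(
    add = list(
      list(id = "R2", metabolites = c(B_c = -1, h2_c = -3, P_c = 1, h2o_c = 1),
           metabolite_formulas = c(P_c = "C3H8O2")),
      list(id = "T_P", metabolites = c(P_c = -1, P_e = 1),
           metabolite_formulas = c(P_e = "C3H8O2")),
      list(id = "EX_P_e", metabolites = c(P_e = -1))
    ),
    product_exchange = "EX_P_e")
}

test_that("the BiGG JSON reader recovers the network structure", {
  m <- toy_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(dim(m$S), c(7, 8))
  expect_equal(m$S["B_c", "R1"], 2)
  expect_equal(m$lb[match("EX_A_e", m$rxn_ids)], -10)
})

test_that("an empty patch leaves the model unchanged", {
  m <- toy_model()
  expect_equal(apply_patch(m, pathway_patch()), m)
})

test_that("unbalanced additions are rejected with the offending element", {
  m <- toy_model()
  bad <- pathway_patch(add = list(
    list(id = "BAD", metabolites = c(B_c = -1, P_c = 1),
         metabolite_formulas = c(P_c = "C3H8O2"))))
  expect_error(apply_patch(m, bad), "unbalanced in.*H")
})

test_that("the LP recovers the analytic optimum of the toy network", {
  # glucose-like substrate fixed at 10: R1 makes 20 B + 20 H2; the product
  # step needs 3 H2 per B, the byproduct route trades 1 B for 5 H2.
  # Cofactor closure 20 + 5c = 3b with b + c = 20 gives b = 15.
  m <- apply_patch(toy_model(), toy_product_patch())
  yld <- theoretical_yield(m, "EX_P_e", glucose_exchange = "EX_A_e")
  expect_equal(yld$flux, 15, tolerance = 1e-9)
  mw_p <- 3 * 12.011 + 8 * 1.008 + 2 * 15.999
  expect_equal(yld$yield_g_g, 15 * mw_p / (10 * 180.156), tolerance = 1e-9)
  expect_lte(yld$carbon_fraction, 1)
  expect_equal(yld$carbon_fraction, 45 / 60, tolerance = 1e-9)
})

test_that("simulated deletions reroute flux through the remaining pathway", {
  # without the byproduct route the cofactor closure is 20 = 3b, b = 20/3
  m <- apply_patch(toy_model(),
                   pathway_patch(add = toy_product_patch()$add,
                                 remove = "R3"))
  yld <- theoretical_yield(m, "EX_P_e", glucose_exchange = "EX_A_e")
  expect_equal(yld$flux, 20 / 3, tolerance = 1e-9)
  expect_error(apply_patch(toy_model(), pathway_patch(remove = "NOPE")),
               "unknown reaction")
})

test_that("the LP solution is deterministic across repeated solves", {
  m <- apply_patch(toy_model(), toy_product_patch())
  a <- theoretical_yield(m, "EX_P_e", glucose_exchange = "EX_A_e")
  b <- theoretical_yield(m, "EX_P_e", glucose_exchange = "EX_A_e")
  expect_identical(a$yield_g_g, b$yield_g_g)
  expect_identical(a$fluxes, b$fluxes)
})

test_that("the diol pathway patches are elementally balanced by construction", {
  # audit against a stub model carrying the BiGG formulas of the touched
  # endogenous metabolites
  formulas <- c(alac__S_c = "C5H7O4", h_c = "H", co2_c = "CO2",
                nadh_c = "C21H27N7O14P2", nad_c = "C21H26N7O14P2",
                `3hbcoa__R_c` = "C25H38N7O18P3S", coa_c = "C21H32N7O16P3S",
                lac__D_c = "C3H5O3", accoa_c = "C23H34N7O17P3S",
                ac_c = "C2H3O2", lald__D_c = "C3H6O2")
  S <- matrix(0, length(formulas) + 1, 1,
              dimnames = list(c(names(formulas), "MGSA_m"), "MGSA"))
  stub <- structure(list(S = S, lb = 0, ub = 1000, rxn_ids = "MGSA",
                         met_ids = rownames(S),
                         met_formulas = c(formulas, MGSA_m = NA)),
                    class = "metabolic_model")
  for (diol in c("2,3-BDO", "1,3-BDO", "1,2-PDO")) {
    patched <- apply_patch(stub, diol_pathway_patch(diol))
    expect_true(diol_pathway_patch(diol)$product_exchange %in% patched$rxn_ids)
  }
})

test_that("experimental yields reproduce their published derivations", {
  tab <- experimental_yield_table()
  expect_equal(tab$yield_g_g[tab$diol == "2,3-BDO"], 73.8 / 171)
  expect_rel(tab$yield_g_g[tab$diol == "2,3-BDO"], 0.432, 0.002)
  expect_rel(tab$yield_g_g[tab$diol == "1,3-BDO"], 0.11, 0.01)
  expect_rel(tab$yield_g_g[tab$diol == "1,2-PDO"], 0.178, 0.005)
  # experimental 2,3-BDO sits at ~80% of the FBA theoretical maximum
  expect_rel(tab$yield_g_g[tab$diol == "2,3-BDO"] / 0.538, 0.80, 0.01)
})

test_that("the SBML fallback reader agrees with the JSON reader", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="mini">
  <listOfParameters>
   <parameter id="lbneg" value="-10" constant="true"/>
   <parameter id="zero" value="0" constant="true"/>
   <parameter id="big" value="1000" constant="true"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="A_e" fbc:chemicalFormula="C6H12O6"
            xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"/>
   <species id="A_c" fbc:chemicalFormula="C6H12O6"
            xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="EX_A_e" reversible="true" lowerFluxBound="lbneg" upperFluxBound="zero">
    <listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>
   </reaction>
   <reaction id="T_A" reversible="false" lowerFluxBound="zero" upperFluxBound="big">
    <listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="A_c" stoichiometry="1"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- read_sbml_model(f)
  expect_equal(dim(m$S), c(2, 2))
  expect_equal(m$S["A_e", "T_A"], -1)
  expect_equal(m$S["A_c", "T_A"], 1)
  expect_equal(m$lb[match("EX_A_e", m$rxn_ids)], -10)
  expect_equal(m$ub[match("T_A", m$rxn_ids)], 1000)
  expect_equal(unname(m$met_formulas["A_e"]), "C6H12O6")
})
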