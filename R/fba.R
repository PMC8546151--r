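# Constraint-based theoretical-yield calculator for short-chain diols.
#
# Reads a genome-scale metabolic model (BiGG-dialect JSON, SBML/FBC
# fallback), grafts an engineered production pathway onto it (with an
# elemental-balance audit of every added reaction), applies the exchange
# constraints (glucose uptake fixed at 10, O2 uptake fixed at 15
# mmol/gDW/h), and maximizes product export by linear programming.

#' Read a metabolic model from BiGG-style JSON
#'
#' @param path Path to a JSON model with `metabolites` (id, formula) and
#'   `reactions` (id, metabolites, lower_bound, upper_bound) arrays.
#' @return An object of class `metabolic_model`: dense stoichiometric matrix
#'   `S` (metabolites x reactions), bounds `lb`/`ub`, `rxn_ids`, `met_ids`,
#'   `met_formulas`.
#' @export
read_bigg_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- vapply(j$metabolites, `[[`, "", "id")
  formulas <- vapply(j$metabolites, function(m)
    if (is.null(m$formula)) NA_character_ else m$formula, "")
  names(formulas) <- mets
  rxns <- vapply(j$reactions, `[[`, "", "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- ub <- numeric(length(rxns))
  for (k in seq_along(j$reactions)) {
    r <- j$reactions[[k]]
    st <- unlist(r$metabolites)
    S[names(st), k] <- st
    lb[k] <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub[k] <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
  }
  .metabolic_model(S, lb, ub, formulas)
}

#' Read a metabolic model from SBML (level 3, fbc package)
#'
#' Minimal SBML reader covering the constructs genome-scale models use:
#' species with `fbc:chemicalFormula`, reactions with reactant/product
#' stoichiometries and fbc flux bounds (via bound parameters).
#'
#' @param path Path to an SBML file.
#' @return A `metabolic_model`.
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- xml2::xml_attr(sp, "id")
  formulas <- xml2::xml_attr(sp, "chemicalFormula")
  names(formulas) <- mets
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- ub <- numeric(length(rxns))
  for (k in seq_along(rx)) {
    r <- rx[[k]]
    for (sref in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      m <- xml2::xml_attr(sref, "species")
      S[m, k] <- S[m, k] - as.numeric(xml2::xml_attr(sref, "stoichiometry"))
    }
    for (sref in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      m <- xml2::xml_attr(sref, "species")
      S[m, k] <- S[m, k] + as.numeric(xml2::xml_attr(sref, "stoichiometry"))
    }
    lbid <- xml2::xml_attr(r, "lowerFluxBound")
    ubid <- xml2::xml_attr(r, "upperFluxBound")
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb[k] <- if (!is.na(lbid) && lbid %in% names(parval)) parval[[lbid]]
             else if (rev) -1000 else 0
    ub[k] <- if (!is.na(ubid) && ubid %in% names(parval)) parval[[ubid]]
             else 1000
  }
  .metabolic_model(S, lb, ub, formulas)
}

.metabolic_model <- function(S, lb, ub, formulas) {
  stopifnot(ncol(S) == length(lb), length(lb) == length(ub))
  structure(list(S = S, lb = lb, ub = ub,
                 rxn_ids = colnames(S), met_ids = rownames(S),
                 met_formulas = formulas),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions\n",
              nrow(x$S), ncol(x$S)))
  invisible(x)
}

# Parse a chemical formula string into a named element-count vector
.parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  n <- sub("^[A-Z][a-z]?", "", parts)
  n[n == ""] <- "1"
  tapply(as.numeric(n), el, sum)
}

# Net element balance of one reaction column; NULL if any formula missing
.element_balance <- function(model, stoich) {
  total <- c()
  for (m in names(stoich)) {
    f <- .parse_formula(model$met_formulas[[m]])
    if (is.null(f)) return(NULL)
    for (el in names(f)) {
      total[el] <- (if (el %in% names(total)) total[el] else 0) +
        stoich[[m]] * f[[el]]
    }
  }
  total
}

#' Define a pathway patch
#'
#' @param add List of added reactions; each a list with `id`, `metabolites`
#'   (named stoichiometry, negative = consumed), optional `lb`/`ub`
#'   (defaults 0/1000), and optional `metabolite_formulas` (named character,
#'   formulas for metabolites new to the model).
#' @param remove Character vector of reaction ids to delete (bounds set to
#'   zero, the simulated gene deletion).
#' @param product_exchange Id of the product exchange reaction (must be among
#'   the added reactions or absent from the base model).
#' @return An object of class `pathway_patch`.
#' @export
pathway_patch <- function(add = list(), remove = character(),
                          product_exchange = NULL) {
  structure(list(add = add, remove = remove,
                 product_exchange = product_exchange),
            class = "pathway_patch")
}

#' Graft a pathway patch onto a model
#'
#' Adds the patch reactions (auditing the elemental balance of every
#' non-exchange addition and erroring with the offending element), registers
#' any new metabolites with their formulas, and zeroes the bounds of deleted
#' reactions.
#'
#' @param model A `metabolic_model`.
#' @param patch A [pathway_patch()].
#' @return The patched `metabolic_model`.
#' @export
apply_patch <- function(model, patch) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(patch, "pathway_patch"))
  for (rx in patch$add) {
    stopifnot(!is.null(rx$id), !is.null(rx$metabolites))
    if (rx$id %in% model$rxn_ids)
      stop("reaction '", rx$id, "' already present in the model")
    newmets <- setdiff(names(rx$metabolites), model$met_ids)
    if (length(newmets)) {
      ff <- rx$metabolite_formulas
      missing_f <- setdiff(newmets, names(ff))
      if (length(missing_f))
        stop("new metabolites without formulas: ",
             paste(missing_f, collapse = ", "))
      model$S <- rbind(model$S,
                       matrix(0, length(newmets), ncol(model$S),
                              dimnames = list(newmets, colnames(model$S))))
      model$met_ids <- rownames(model$S)
      model$met_formulas[newmets] <- ff[newmets]
    }
    is_exchange <- length(rx$metabolites) == 1
    if (!is_exchange) {
      bal <- .element_balance(model, rx$metabolites)
      if (!is.null(bal)) {
        off <- names(bal)[abs(bal) > 1e-6]
        if (length(off))
          stop("added reaction '", rx$id, "' is elementally unbalanced in: ",
               paste(off, collapse = ", "))
      }
    }
    col <- numeric(nrow(model$S))
    names(col) <- rownames(model$S)
    col[names(rx$metabolites)] <- unlist(rx$metabolites)
    model$S <- cbind(model$S, col)
    colnames(model$S)[ncol(model$S)] <- rx$id
    model$rxn_ids <- colnames(model$S)
    model$lb <- c(model$lb, if (is.null(rx$lb)) 0 else rx$lb)
    model$ub <- c(model$ub, if (is.null(rx$ub)) 1000 else rx$ub)
  }
  for (rid in patch$remove) {
    k <- match(rid, model$rxn_ids)
    if (is.na(k)) stop("cannot delete unknown reaction '", rid, "'")
    model$lb[k] <- 0; model$ub[k] <- 0
  }
  model
}

# Two-phase dense simplex with Bland's anti-cycling rule.
# Solves min cost' x subject to A x = b, x >= 0. Returns x or errors.
.simplex_solve <- function(cost, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)          # artificial columns
  pivot_run <- function(tab, basis, cost_ext, allowed) {
    ncols <- ncol(tab) - 1
    repeat {
      cb <- cost_ext[basis]
      red <- as.vector(cb %*% tab[, seq_len(ncols), drop = FALSE]) -
        cost_ext[seq_len(ncols)]
      cand <- which(red > tol & allowed)
      if (!length(cand)) return(list(tab = tab, basis = basis))
      j <- min(cand)                       # Bland's rule
      col <- tab[, j]; rhs <- tab[, ncols + 1]
      ratio <- ifelse(col > tol, rhs / col, Inf)
      if (!any(is.finite(ratio))) stop("unbounded linear program")
      i_cand <- which(ratio <= min(ratio) + 0)
      i <- i_cand[which.min(basis[i_cand])] # Bland's rule on leaving var
      tab[i, ] <- tab[i, ] / tab[i, j]
      for (r in seq_len(nrow(tab)))
        if (r != i) tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
      basis[i] <- j
    }
  }
  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(1, m))
  res <- pivot_run(tab, basis, cost1, rep(TRUE, n + m))
  tab <- res$tab; basis <- res$basis
  if (sum(tab[, ncol(tab)][basis > n]) > 1e-7)
    stop("infeasible linear program")
  # pivot residual artificials out of the basis where possible
  for (i in which(basis > n)) {
    piv <- which(abs(tab[i, seq_len(n)]) > tol)
    if (length(piv)) {
      j <- piv[1]
      tab[i, ] <- tab[i, ] / tab[i, j]
      for (r in seq_len(nrow(tab)))
        if (r != i) tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
      basis[i] <- j
    }
  }
  # phase 2 over the original columns only
  allowed <- c(rep(TRUE, n), rep(FALSE, m))
  cost2 <- c(cost, rep(0, m))
  res <- pivot_run(tab, basis, cost2, allowed)
  tab <- res$tab; basis <- res$basis
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- tab[keep, ncol(tab)]
  x
}

#' Solve a flux-balance linear program
#'
#' Maximizes (or minimizes) the flux through one reaction subject to
#' steady-state mass balance `S v = 0` and the flux bounds. Solved with a
#' built-in two-phase simplex (Bland's rule) on shifted non-negative
#' variables with slack columns for the upper bounds, which keeps the solve
#' deterministic across restarts.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id to optimize.
#' @param maximize Direction (default maximize).
#' @return A list with `objective_value` and the full `fluxes` vector.
#' @export
fba_optimize <- function(model, objective, maximize = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  k <- match(objective, model$rxn_ids)
  if (is.na(k)) stop("objective reaction '", objective, "' not in model")
  lb <- pmax(model$lb, -1000); ub <- pmin(model$ub, 1000)
  if (any(lb > ub)) stop("infeasible bounds (lb > ub)")
  n <- length(lb)
  # fixed variables (lb == ub, e.g. deletions and pinned exchanges) are
  # substituted out before the solve
  free <- which(ub - lb > 1e-12)
  fixed <- setdiff(seq_len(n), free)
  rhs <- -as.vector(model$S %*% ifelse(seq_len(n) %in% fixed, lb, 0))
  Sf <- model$S[, free, drop = FALSE]
  beq <- rhs - as.vector(Sf %*% lb[free])
  keep <- rowSums(abs(Sf)) > 0
  if (any(!keep & abs(beq) > 1e-9))
    stop("infeasible LP: fixed fluxes violate steady state")
  cc <- numeric(length(free)); cc[match(k, free)] <- 1
  if (k %in% fixed) {
    v <- lb; v[fixed] <- lb[fixed]
    return(list(objective_value = unname(v[k]),
                fluxes = stats::setNames(v, model$rxn_ids)))
  }
  nf <- length(free)
  # standard form: [Sf 0; I I] [x; s] = [beq; ub - lb], x, s >= 0
  Aeq <- Sf[keep, , drop = FALSE]
  A_std <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), nf)),
                 cbind(diag(nf), diag(nf)))
  b_std <- c(beq[keep], (ub - lb)[free])
  cost <- c(if (maximize) -cc else cc, rep(0, nf))
  x_std <- .simplex_solve(cost, A_std, b_std)
  v <- numeric(n)
  v[fixed] <- lb[fixed]
  v[free] <- x_std[seq_len(nf)] + lb[free]
  resid <- max(abs(model$S %*% v))
  if (resid > 1e-6)
    stop(sprintf("LP solution violates steady state (residual %.2e)", resid))
  list(objective_value = unname(v[k]), fluxes = stats::setNames(v, model$rxn_ids))
}

#' Theoretical product yield from glucose
#'
#' Fixes glucose uptake at 10 and O2 uptake at 15 mmol/gDW/h (equality by
#' default, a lower bound with `o2_constraint = "bound"`), maximizes the
#' product exchange flux, audits the carbon balance of the solution (product
#' carbon cannot exceed glucose carbon uptake), and converts to a mass yield.
#'
#' @param model A patched `metabolic_model`.
#' @param product_exchange Product exchange reaction id.
#' @param product_mw Product molar mass, g/mol; inferred from the exchanged
#'   metabolite's formula when `NULL`.
#' @param glucose_exchange,o2_exchange Exchange reaction ids.
#' @param glucose_uptake,o2_uptake Uptake magnitudes, mmol/gDW/h.
#' @param o2_constraint `"fixed"` (equality) or `"bound"` (at most).
#' @return A list with `yield_g_g`, `flux`, and `carbon_fraction` (product
#'   carbon over glucose carbon).
#' @export
theoretical_yield <- function(model, product_exchange, product_mw = NULL,
                              glucose_exchange = "EX_glc__D_e",
                              o2_exchange = "EX_o2_e",
                              glucose_uptake = 10, o2_uptake = 15,
                              o2_constraint = c("fixed", "bound")) {
  stopifnot(inherits(model, "metabolic_model"))
  o2_constraint <- match.arg(o2_constraint)
  for (id in c(product_exchange, glucose_exchange)) {
    if (!id %in% model$rxn_ids) stop("reaction '", id, "' not in model")
  }
  gk <- match(glucose_exchange, model$rxn_ids)
  model$lb[gk] <- model$ub[gk] <- -glucose_uptake
  if (o2_exchange %in% model$rxn_ids) {
    ok <- match(o2_exchange, model$rxn_ids)
    model$lb[ok] <- -o2_uptake
    model$ub[ok] <- if (o2_constraint == "fixed") -o2_uptake else 0
  }
  sol <- fba_optimize(model, product_exchange, maximize = TRUE)
  pk <- match(product_exchange, model$rxn_ids)
  pmet <- names(which(model$S[, pk] != 0))
  if (length(pmet) != 1)
    stop("product exchange must involve exactly one metabolite")
  f <- .parse_formula(model$met_formulas[[pmet]])
  if (is.null(product_mw)) {
    if (is.null(f)) stop("no formula for '", pmet, "'; supply product_mw")
    known <- .atomic_weights[names(f)]
    if (anyNA(known)) stop("cannot infer molar mass of '", pmet, "'")
    product_mw <- sum(f * known)
  }
  carbon_frac <- NA_real_
  if (!is.null(f) && "C" %in% names(f)) {
    c_prod <- sol$objective_value * f[["C"]]
    c_glc <- glucose_uptake * 6
    carbon_frac <- c_prod / c_glc
    if (carbon_frac > 1 + 1e-9)
      stop("carbon balance violated: product carbon exceeds glucose carbon")
  }
  yield <- sol$objective_value * product_mw / (glucose_uptake * .MW_GLUCOSE)
  list(yield_g_g = yield, flux = sol$objective_value,
       carbon_fraction = unname(carbon_frac), fluxes = sol$fluxes)
}

#' Engineered diol pathway patches
#'
#' Reconstruction of the three production pathways grafted onto the E. coli
#' genome-scale model: 2,3-butanediol from (S)-2-acetolactate (acetolactate
#' decarboxylase, then acetoin reductase), 1,3-butanediol from
#' (R)-3-hydroxybutyryl-CoA (CoA-acylating aldehyde dehydrogenase, then
#' alcohol dehydrogenase), and 1,2-propanediol from D-lactate (CoA
#' transferase, CoA-acylating aldehyde dehydrogenase, then lactaldehyde
#' reductase), with the native methylglyoxal route deleted for 1,2-PDO.
#' Metabolite ids follow the BiGG namespace of iML1515.
#'
#' @param diol One of `"2,3-BDO"`, `"1,3-BDO"`, `"1,2-PDO"`.
#' @return A [pathway_patch()].
#' @export
diol_pathway_patch <- function(diol = c("2,3-BDO", "1,3-BDO", "1,2-PDO")) {
  diol <- match.arg(diol)
  switch(diol,
    "2,3-BDO" = pathway_patch(
      add = list(
        list(id = "ACLDC_het",
             metabolites = c(alac__S_c = -1, h_c = -1, actn__R_c = 1,
                             co2_c = 1),
             metabolite_formulas = c(actn__R_c = "C4H8O2")),
        list(id = "BTDD_RR_het",
             metabolites = c(actn__R_c = -1, h_c = -1, nadh_c = -1,
                             btd_RR_c = 1, nad_c = 1),
             metabolite_formulas = c(btd_RR_c = "C4H10O2")),
        list(id = "BTDt_het", lb = -1000,
             metabolites = c(btd_RR_c = -1, btd_RR_e = 1),
             metabolite_formulas = c(btd_RR_e = "C4H10O2")),
        list(id = "EX_btd_RR_e", metabolites = c(btd_RR_e = -1))
      ),
      product_exchange = "EX_btd_RR_e"),
    "1,3-BDO" = pathway_patch(
      add = list(
        list(id = "HBCOAR_het",
             metabolites = c(`3hbcoa__R_c` = -1, h_c = -1, nadh_c = -1,
                             `3hbal_c` = 1, nad_c = 1, coa_c = 1),
             metabolite_formulas = c(`3hbal_c` = "C4H8O2")),
        list(id = "BDH13_het",
             metabolites = c(`3hbal_c` = -1, h_c = -1, nadh_c = -1,
                             bdo13_c = 1, nad_c = 1),
             metabolite_formulas = c(bdo13_c = "C4H10O2")),
        list(id = "BDO13t_het", lb = -1000,
             metabolites = c(bdo13_c = -1, bdo13_e = 1),
             metabolite_formulas = c(bdo13_e = "C4H10O2")),
        list(id = "EX_bdo13_e", metabolites = c(bdo13_e = -1))
      ),
      product_exchange = "EX_bdo13_e"),
    "1,2-PDO" = pathway_patch(
      add = list(
        list(id = "LCTCOAT_het",
             metabolites = c(lac__D_c = -1, accoa_c = -1, laccoa_c = 1,
                             ac_c = 1),
             metabolite_formulas = c(laccoa_c = "C24H36N7O18P3S")),
        list(id = "LALDH_het",
             metabolites = c(laccoa_c = -1, h_c = -1, nadh_c = -1,
                             lald__D_c = 1, nad_c = 1, coa_c = 1)),
        list(id = "PDOR_het",
             metabolites = c(lald__D_c = -1, h_c = -1, nadh_c = -1,
                             ppd12_c = 1, nad_c = 1),
             metabolite_formulas = c(ppd12_c = "C3H8O2")),
        list(id = "PPD12t_het", lb = -1000,
             metabolites = c(ppd12_c = -1, ppd12_e = 1),
             metabolite_formulas = c(ppd12_e = "C3H8O2")),
        list(id = "EX_ppd12_e", metabolites = c(ppd12_e = -1))
      ),
      remove = c("MGSA"),   # methylglyoxal synthase (native route)
      product_exchange = "EX_ppd12_e")
  )
}

#' Experimental diol yields from the fermentation literature
#'
#' Reference experimental yields and their derivations: 1,2-PDO from the
#' reported molar yield (0.422 mol/mol glucose), 1,3-BDO and 2,3-BDO from
#' reported fed-batch titers over glucose consumed (9.05/83.05 and 73.8/171
#' g/L respectively).
#'
#' @return A data frame with `diol`, `yield_g_g` and `derivation`.
#' @examples
#' experimental_yield_table()
#' @export
experimental_yield_table <- function() {
  mw_pdo <- 3 * .atomic_weights[["C"]] + 8 * .atomic_weights[["H"]] +
    2 * .atomic_weights[["O"]]
  data.frame(
    diol = c("1,2-PDO", "1,3-BDO", "2,3-BDO"),
    yield_g_g = c(0.422 * mw_pdo / .MW_GLUCOSE, 9.05 / 83.05, 73.8 / 171),
    derivation = c("0.422 mol/mol x 76.09/180.16",
                   "9.05 g/L titer / 83.05 g/L glucose",
                   "73.8 g/L titer / 171 g/L glucose"),
    stringsAsFactors = FALSE
  )
}
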