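# SBML import (Level 3 core / Level 2 subset) and a subset writer.
#
# Supported: species, constant-size compartments, global and local
# parameters, reactions with kinetic laws, assignment rules on parameters
# (substituted symbolically), rate rules, initial assignments. Rejected with
# errors naming the construct: events, delays, algebraic rules, fast
# reactions, function definitions, non-constant compartments,
# stoichiometryMath, assignment rules on species, multi-compartment
# reactions. Species are interpreted in concentration units; amount-based
# initial values and kinetic laws are divided by the (constant) compartment
# size at import, so f = S v holds for the stored fluxes.

malformed_document <- function(msg) {
  stop(errorCondition(paste0("malformed SBML document: ", msg),
                      class = "odesens_malformed_document"))
}

unsupported_feature <- function(features) {
  msg <- paste0("unsupported SBML feature(s): ",
                paste(sprintf("%s (%s): %s", features$construct,
                              features$location, features$message),
                      collapse = "; "))
  stop(errorCondition(msg, features = features,
                      class = "odesens_unsupported_feature"))
}

attr_or <- function(node, attr, default) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

num_attr <- function(node, attr, default = NA_real_) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else as.numeric(v)
}

find_math <- function(node) {
  m <- xml2::xml_find_first(node, "./math")
  if (inherits(m, "xml_missing")) NULL else m
}

#' Import an SBML reaction network as a symbolic ODE model
#'
#' Builds the right-hand side as `S v` from reactions plus any rate rules.
#' Compartment sizes become fixed parameters (their numeric value is folded
#' into amount-rate kinetic laws and amount initial values, establishing the
#' internal concentration convention). Initial assignments override plain
#' initial values; assignment rules on parameters are substituted
#' symbolically; species with `boundaryCondition="true"` (or
#' `constant="true"`) get zero rows in the stoichiometric matrix. Unit
#' annotations are ignored: values are taken at face.
#'
#' @param document path to an SBML file, or a string containing the XML.
#' @param fixed_ids parameter ids to treat as fixed (condition-settable)
#'   constants `k` instead of dynamic parameters `p`.
#' @return an `ode_model` (observables empty; attach with
#'   [set_observables()]).
#' @export
import_sbml <- function(document, fixed_ids = character(0)) {
  doc <- tryCatch(
    if (is.character(document) && length(document) == 1L &&
        grepl("^\\s*<", document)) xml2::read_xml(document)
    else xml2::read_xml(document),
    error = function(e) malformed_document(conditionMessage(e)))
  root <- xml2::xml_ns_strip(doc)
  if (xml2::xml_name(root) != "sbml")
    malformed_document("root element is not <sbml>")
  level <- suppressWarnings(as.integer(xml2::xml_attr(root, "level")))
  if (is.na(level) || !(level %in% c(2L, 3L)))
    malformed_document("only SBML Level 2/3 documents are supported")
  model_node <- xml2::xml_find_first(root, "./model")
  if (inherits(model_node, "xml_missing"))
    malformed_document("document contains no <model>")

  feats <- data.frame(construct = character(0), location = character(0),
                      message = character(0))
  flag <- function(construct, location, message) {
    feats[nrow(feats) + 1L, ] <<- list(construct, location, message)
  }

  # Structural constructs outside the ODE-only subset
  for (ev in xml2::xml_find_all(model_node, ".//event"))
    flag("event", attr_or(ev, "id", "listOfEvents"),
         "events are not supported (ODE-only subset)")
  for (fd in xml2::xml_find_all(model_node, ".//functionDefinition"))
    flag("functionDefinition", attr_or(fd, "id", "listOfFunctionDefinitions"),
         "function definitions are not supported")
  for (ar in xml2::xml_find_all(model_node, ".//algebraicRule"))
    flag("algebraicRule", "listOfRules",
         "algebraic rules are not supported")
  for (cs in xml2::xml_find_all(model_node, ".//constraint"))
    flag("constraint", "listOfConstraints",
         "constraints are not supported")
  for (d in xml2::xml_find_all(model_node, ".//csymbol")) {
    if (grepl("delay", attr_or(d, "definitionURL", "")))
      flag("delay", "math", "delay terms are not supported")
  }

  parse_math <- function(node, where) {
    tryCatch(mathml_to_expr(node), error = function(e) {
      flag("math", where, conditionMessage(e))
      0
    })
  }

  # compartments
  comp_size <- numeric(0)
  for (cn in xml2::xml_find_all(model_node,
                                "./listOfCompartments/compartment")) {
    id <- xml2::xml_attr(cn, "id")
    if (identical(attr_or(cn, "constant", "true"), "false"))
      flag("non-constant compartment", id,
           "compartments with varying size are not supported")
    comp_size[id] <- num_attr(cn, "size", num_attr(cn, "volume", 1))
    if (is.na(comp_size[id])) comp_size[id] <- 1
  }

  # species
  sp_nodes <- xml2::xml_find_all(model_node, "./listOfSpecies/species")
  species <- list()
  for (sn in sp_nodes) {
    id <- xml2::xml_attr(sn, "id")
    comp <- xml2::xml_attr(sn, "compartment")
    if (!is.na(comp) && length(comp_size) && !(comp %in% names(comp_size)))
      malformed_document(sprintf("species '%s' references unknown compartment '%s'",
                                 id, comp))
    vol <- if (!is.na(comp) && comp %in% names(comp_size))
      comp_size[[comp]] else 1
    conc <- num_attr(sn, "initialConcentration")
    amt <- num_attr(sn, "initialAmount")
    x0 <- if (!is.na(conc)) conc else if (!is.na(amt)) amt / vol else 0
    species[[id]] <- list(id = id, comp = comp, vol = vol, x0 = x0,
      boundary = identical(attr_or(sn, "boundaryCondition", "false"), "true") ||
                 identical(attr_or(sn, "constant", "false"), "true"))
  }

  # global parameters
  params <- numeric(0)
  for (pn in xml2::xml_find_all(model_node, "./listOfParameters/parameter")) {
    id <- xml2::xml_attr(pn, "id")
    params[id] <- num_attr(pn, "value", 0)
  }

  # rules
  assign_rules <- list()
  rate_rules <- list()
  for (rn in xml2::xml_find_all(model_node, "./listOfRules/assignmentRule")) {
    var <- xml2::xml_attr(rn, "variable")
    if (var %in% names(species)) {
      flag("assignment rule on species", var,
           "species defined by assignment rules are not supported")
      next
    }
    m <- find_math(rn)
    if (!is.null(m)) assign_rules[[var]] <- parse_math(m, paste0("rule ", var))
  }
  for (rn in xml2::xml_find_all(model_node, "./listOfRules/rateRule")) {
    var <- xml2::xml_attr(rn, "variable")
    m <- find_math(rn)
    if (!is.null(m)) rate_rules[[var]] <- parse_math(m, paste0("rateRule ", var))
  }

  # initial assignments
  init_assign <- list()
  for (ia in xml2::xml_find_all(model_node,
                                "./listOfInitialAssignments/initialAssignment")) {
    sym <- xml2::xml_attr(ia, "symbol")
    m <- find_math(ia)
    if (!is.null(m))
      init_assign[[sym]] <- parse_math(m, paste0("initialAssignment ", sym))
  }

  # reactions
  rx_nodes <- xml2::xml_find_all(model_node, "./listOfReactions/reaction")
  n_rx <- length(rx_nodes)
  fluxes <- vector("list", n_rx)
  rx_ids <- character(n_rx)
  stoich <- list()  # species -> named numeric over reactions
  local_params <- numeric(0)
  for (j in seq_len(n_rx)) {
    rn <- rx_nodes[[j]]
    rid <- attr_or(rn, "id", paste0("reaction_", j))
    rx_ids[j] <- rid
    if (identical(attr_or(rn, "fast", "false"), "true"))
      flag("fast reaction", rid, "fast reactions are not supported")
    refs <- function(xpath, sign) {
      for (sr in xml2::xml_find_all(rn, xpath)) {
        sid <- xml2::xml_attr(sr, "species")
        if (!(sid %in% names(species)))
          malformed_document(sprintf(
            "reaction '%s' references unknown species '%s'", rid, sid))
        if (length(xml2::xml_find_all(sr, "./stoichiometryMath")))
          flag("stoichiometryMath", rid,
               "stoichiometryMath is not supported")
        st <- num_attr(sr, "stoichiometry", 1)
        cur <- stoich[[sid]]
        if (is.null(cur)) cur <- numeric(n_rx)
        cur[j] <- cur[j] + sign * st
        stoich[[sid]] <<- cur
      }
    }
    refs("./listOfReactants/speciesReference", -1)
    refs("./listOfProducts/speciesReference", +1)

    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    if (inherits(kl, "xml_missing")) {
      flag("missing kinetic law", rid, "reaction lacks a kinetic law")
      next
    }
    m <- find_math(kl)
    law <- if (is.null(m)) {
      flag("missing kinetic law", rid, "kinetic law lacks math")
      0
    } else parse_math(m, paste0("reaction ", rid))
    # local parameters -> globally unique ids
    loc <- c(xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter"),
             xml2::xml_find_all(kl, "./listOfParameters/parameter"))
    if (length(loc)) {
      ren <- list()
      for (lp in loc) {
        lid <- xml2::xml_attr(lp, "id")
        gid <- paste0(rid, "_", lid)
        local_params[gid] <- num_attr(lp, "value", 0)
        ren[[lid]] <- as.name(gid)
      }
      law <- subst_expr(law, ren)
    }
    # fold compartment size: participants must share one compartment
    part <- names(stoich)[vapply(stoich, function(v) v[j] != 0, logical(1L))]
    vols <- unique(vapply(part, function(s) species[[s]]$vol, numeric(1L)))
    comps <- unique(unlist(lapply(part, function(s) species[[s]]$comp)))
    comps <- comps[!is.na(comps)]
    if (length(comps) > 1L)
      flag("multi-compartment reaction", rid,
           "reactions spanning compartments are not supported")
    if (length(vols) == 1L && vols[1L] != 1)
      law <- simplify_expr(call("/", law, vols[1L]))
    fluxes[[j]] <- law
  }

  if (nrow(feats)) unsupported_feature(feats)

  # assemble states: species plus parameters promoted by rate rules
  promoted <- intersect(names(rate_rules), names(params))
  states <- c(names(species), promoted)
  S <- matrix(0, length(states), n_rx,
              dimnames = list(states, rx_ids))
  for (sid in names(stoich))
    if (!species[[sid]]$boundary) S[sid, ] <- stoich[[sid]]
  rhs <- if (n_rx) reactions_to_odes(S, fluxes) else
    rep(list(0), length(states))
  names(rhs) <- states
  x0 <- stats::setNames(lapply(species, function(s) s$x0), names(species))
  for (pid in promoted) {
    x0[[pid]] <- unname(params[[pid]])
    params <- params[setdiff(names(params), pid)]
  }
  for (var in names(rate_rules)) {
    if (!(var %in% states))
      malformed_document(sprintf("rate rule targets unknown variable '%s'", var))
    rhs[[var]] <- rate_rules[[var]]
  }

  # initial assignments override plain initial values
  for (sym in names(init_assign)) {
    if (sym %in% states) {
      x0[[sym]] <- init_assign[[sym]]
    } else if (sym %in% names(params)) {
      v <- tryCatch(eval(init_assign[[sym]],
                         as.list(c(params, comp_size)), baseenv()),
                    error = function(e) NA_real_)
      if (is.na(v))
        malformed_document(sprintf(
          "initial assignment for parameter '%s' is not numerically resolvable",
          sym))
      params[sym] <- v
    }
  }

  # substitute assignment rules to a fixed point
  if (length(assign_rules)) {
    params <- params[setdiff(names(params), names(assign_rules))]
    sub_map <- lapply(assign_rules, identity)
    for (iter in seq_len(10L)) {
      changed <- FALSE
      sub_once <- function(e) {
        e2 <- simplify_expr(subst_expr(e, sub_map))
        if (!identical(e2, e)) changed <<- TRUE
        e2
      }
      rhs <- lapply(rhs, sub_once)
      x0 <- lapply(x0, sub_once)
      fluxes <- lapply(fluxes, sub_once)
      sub_map <- lapply(sub_map, sub_once)
      if (!changed) break
      if (iter == 10L)
        malformed_document("cyclic assignment rules")
    }
  }

  params <- c(params, local_params)
  fixed <- comp_size
  extra_fixed <- intersect(fixed_ids, names(params))
  fixed <- c(fixed, params[extra_fixed])
  params <- params[setdiff(names(params), extra_fixed)]

  ode_model(states = states, rhs = rhs[states], x0 = x0[states],
            parameters = params, fixed = fixed,
            stoichiometry = if (n_rx) S else NULL,
            fluxes = if (n_rx) fluxes else NULL,
            name = attr_or(model_node, "id", "sbml_model"))
}

#' Write a model to SBML Level 3 Version 2 (supported subset)
#'
#' Serializes a model built from reactions (stoichiometry + fluxes) as SBML
#' reactions; models without reaction structure are written as rate rules.
#' All species go into one size-1 compartment; non-numeric initial values
#' become initial assignments.
#'
#' @param m an `ode_model`.
#' @param file path to write; when `NULL` the XML string is returned.
#' @return the XML string, invisibly when written to a file.
#' @export
write_sbml <- function(m, file = NULL) {
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  sp <- character(0); ia <- character(0)
  for (s in m$states) {
    v <- m$x0[[s]]
    if (is_num(v)) {
      sp <- c(sp, sprintf(
        '      <species id="%s" compartment="compartment_" initialConcentration="%.17g" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
        s, v))
    } else {
      sp <- c(sp, sprintf(
        '      <species id="%s" compartment="compartment_" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
        s))
      ia <- c(ia, sprintf(
        '      <initialAssignment symbol="%s">%s</initialAssignment>',
        s, expr_to_mathml(v)))
    }
  }
  pars <- c(
    vapply(names(m$parameters), function(id) sprintf(
      '      <parameter id="%s" value="%.17g" constant="true"/>',
      id, m$parameters[[id]]), character(1L)),
    vapply(setdiff(names(m$fixed), "compartment_"), function(id) sprintf(
      '      <parameter id="%s" value="%.17g" constant="true"/>',
      id, m$fixed[[id]]), character(1L)))

  body <- character(0)
  if (!is.null(m$stoichiometry) && !is.null(m$fluxes)) {
    rx <- character(0)
    S <- m$stoichiometry
    rids <- colnames(S)
    if (is.null(rids)) rids <- paste0("reaction_", seq_len(ncol(S)))
    for (j in seq_len(ncol(S))) {
      reac <- rownames(S)[S[, j] < 0]
      prod <- rownames(S)[S[, j] > 0]
      refs <- function(ids, sign) paste(vapply(ids, function(s) sprintf(
        '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
        s, abs(S[s, j])), character(1L)), collapse = "\n")
      rx <- c(rx, sprintf(
'      <reaction id="%s" reversible="false">
%s%s        <kineticLaw>%s</kineticLaw>
      </reaction>',
        rids[j],
        if (length(reac)) sprintf("        <listOfReactants>\n%s\n        </listOfReactants>\n", refs(reac, -1)) else "",
        if (length(prod)) sprintf("        <listOfProducts>\n%s\n        </listOfProducts>\n", refs(prod, +1)) else "",
        expr_to_mathml(m$fluxes[[j]])))
    }
    body <- sprintf("    <listOfReactions>\n%s\n    </listOfReactions>",
                    paste(rx, collapse = "\n"))
  } else {
    rr <- vapply(seq_along(m$states), function(i) sprintf(
      '      <rateRule variable="%s">%s</rateRule>',
      m$states[i], expr_to_mathml(m$rhs[[i]])), character(1L))
    body <- sprintf("    <listOfRules>\n%s\n    </listOfRules>",
                    paste(rr, collapse = "\n"))
  }

  xml <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="%s">
    <listOfCompartments>
      <compartment id="compartment_" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
%s
    </listOfSpecies>
%s%s%s
  </model>
</sbml>
', esc(m$name), paste(sp, collapse = "\n"),
   if (length(pars)) sprintf("    <listOfParameters>\n%s\n    </listOfParameters>\n",
                             paste(pars, collapse = "\n")) else "",
   if (length(ia)) sprintf("    <listOfInitialAssignments>\n%s\n    </listOfInitialAssignments>\n",
                           paste(ia, collapse = "\n")) else "",
   body)
  if (is.null(file)) return(xml)
  writeLines(xml, file)
  invisible(xml)
}
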