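## SBML (Level 2 / Level 3) reading.
##
## Kinetic laws are accepted when, after substituting numeric parameter
## values, their MathML expands to a polynomial with real coefficients in
## the dynamic species; each expanded term becomes one rate monomial.
## Anything else raises a condition of class "tropicaleq_nonpolynomial"
## carrying the offending reaction id.

nonpolynomial_error <- function(reaction_id, why) {
  stop(structure(class = c("tropicaleq_nonpolynomial", "error", "condition"),
                 list(message = sprintf(
                        "non-polynomial kinetics in reaction '%s': %s",
                        reaction_id, why),
                      call = NULL, reaction = reaction_id)))
}

## ---- tiny multivariate polynomial algebra (terms keyed by exponents) ----

p_key <- function(e) if (!length(e)) "1" else {
  e <- e[order(names(e))]
  paste(names(e), e, sep = "^", collapse = "*")
}
p_const <- function(c) {
  if (c == 0) return(structure(list(), class = "tpoly"))
  structure(stats::setNames(list(list(coef = c, exp = stats::setNames(integer(), character()))), "1"),
            class = "tpoly")
}
p_var <- function(name) {
  e <- stats::setNames(1L, name)
  structure(stats::setNames(list(list(coef = 1, exp = e)), p_key(e)), class = "tpoly")
}
p_add <- function(a, b) {
  out <- unclass(a)
  for (k in names(b)) {
    if (k %in% names(out)) {
      out[[k]]$coef <- out[[k]]$coef + b[[k]]$coef
      if (abs(out[[k]]$coef) < 1e-300) out[[k]] <- NULL
    } else out[[k]] <- b[[k]]
  }
  structure(out, class = "tpoly")
}
p_scale <- function(a, s) {
  if (s == 0) return(p_const(0))
  structure(lapply(unclass(a), function(t) { t$coef <- t$coef * s; t }),
            class = "tpoly")
}
p_mul <- function(a, b) {
  out <- p_const(0)
  for (ta in unclass(a)) for (tb in unclass(b)) {
    e <- ta$exp
    for (n in names(tb$exp)) e[n] <- (if (n %in% names(e)) e[[n]] else 0L) + tb$exp[[n]]
    k <- p_key(e)
    cur <- unclass(out)
    if (k %in% names(cur)) {
      cur[[k]]$coef <- cur[[k]]$coef + ta$coef * tb$coef
    } else cur[[k]] <- list(coef = ta$coef * tb$coef, exp = e)
    out <- structure(cur, class = "tpoly")
  }
  structure(Filter(function(t) abs(t$coef) > 0, unclass(out)), class = "tpoly")
}
p_pow <- function(a, n) {
  out <- p_const(1)
  for (i in seq_len(n)) out <- p_mul(out, a)
  out
}
p_is_const <- function(a) length(a) == 0 || (length(a) == 1 && names(a)[1] == "1")
p_const_value <- function(a) if (length(a) == 0) 0 else a[["1"]]$coef

## ---- MathML -> polynomial over the dynamic species ----

## env: named numeric vector of resolved constants (parameters, compartment
## sizes, boundary-species concentrations); dynamic: species identifiers.
mathml_poly <- function(node, env, dynamic, rid) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) nonpolynomial_error(rid, "empty or compound math element")
    return(mathml_poly(kids[[1]], env, dynamic, rid))
  }
  if (name == "ci") {
    id <- trimws(xml2::xml_text(node))
    if (id %in% dynamic) return(p_var(id))
    if (id %in% names(env)) return(p_const(env[[id]]))
    nonpolynomial_error(rid, paste0("unresolved symbol '", id, "'"))
  }
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    txt <- xml2::xml_text(node)
    if (!is.na(type) && type %in% c("rational", "e-notation")) {
      parts <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
      v <- if (type == "rational") parts[1] / parts[2] else parts[1] * 10^parts[2]
      return(p_const(v))
    }
    return(p_const(as.numeric(txt)))
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- kids[-1]
    polys <- function() lapply(args, mathml_poly, env = env, dynamic = dynamic, rid = rid)
    switch(op,
      plus = Reduce(p_add, polys(), p_const(0)),
      times = Reduce(p_mul, polys(), p_const(1)),
      minus = {
        ps <- polys()
        if (length(ps) == 1) p_scale(ps[[1]], -1)
        else p_add(ps[[1]], p_scale(ps[[2]], -1))
      },
      divide = {
        ps <- polys()
        if (!p_is_const(ps[[2]]))
          nonpolynomial_error(rid, "division by a species-dependent expression")
        d <- p_const_value(ps[[2]])
        if (d == 0) nonpolynomial_error(rid, "division by zero")
        p_scale(ps[[1]], 1 / d)
      },
      power = {
        ps <- polys()
        if (!p_is_const(ps[[2]]))
          nonpolynomial_error(rid, "species-dependent exponent")
        n <- p_const_value(ps[[2]])
        if (!is_wholenumber(n) || n < 0)
          nonpolynomial_error(rid, "non-integer or negative exponent")
        p_pow(ps[[1]], round(n))
      },
      nonpolynomial_error(rid, paste0("operator '", op, "'"))
    )
  } else nonpolynomial_error(rid, paste0("MathML element '", name, "'"))
}

xml_num_attr <- function(node, ...) {
  for (a in c(...)) {
    v <- xml2::xml_attr(node, a)
    if (!is.na(v)) return(as.numeric(v))
  }
  NA_real_
}

#' Read a reaction network from an SBML file
#'
#' Supports SBML Level 2 and Level 3 with polynomial (expandable
#' mass-action) kinetic laws.  Global and local parameters are resolved
#' numerically; species flagged `boundaryCondition` or `constant` are folded
#' into the rate constants as fixed parameters; compartment volumes are
#' folded into the effective rate constants (all compartments must have
#' equal size).  Each expanded kinetic-law term of reaction \eqn{j} becomes
#' one generalized reaction carrying the term's kinetic exponents and the
#' reaction's net stoichiometry (negated for negative terms, as for the
#' reverse direction of a reversible law).  A kinetic law that does not
#' expand to a polynomial in the dynamic species raises an error of class
#' `tropicaleq_nonpolynomial` carrying the offending reaction id.  SBML
#' events are ignored with a warning; assignment, rate and algebraic rules
#' whose targets feed the kinetics trigger the non-polynomial rejection.
#'
#' @param path path to an SBML file.
#' @return a [reaction_network()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)   # malformed XML errors out here
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model> in ", path)

  if (length(xml2::xml_find_all(model, ".//listOfEvents/event")))
    warning("SBML events present; ignored")

  ## rules: constant assignment rules are folded in, anything else is a
  ## potential non-polynomial dependency
  rule_vals <- numeric(); bad_rule_targets <- character()
  for (r in xml2::xml_find_all(model, ".//listOfRules/*")) {
    tgt <- xml2::xml_attr(r, "variable")
    math <- xml2::xml_find_first(r, "./math")
    kids <- if (!inherits(math, "xml_missing")) xml2::xml_children(math)
    if (xml2::xml_name(r) == "assignmentRule" && !is.null(kids) &&
        length(kids) == 1 && xml2::xml_name(kids[[1]]) == "cn") {
      rule_vals[tgt] <- as.numeric(xml2::xml_text(kids[[1]]))
    } else bad_rule_targets <- c(bad_rule_targets, tgt %||% "<algebraic>")
  }

  comps <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  comp_size <- stats::setNames(
    vapply(comps, function(c) {
      s <- xml_num_attr(c, "size", "volume")
      if (is.na(s)) 1 else s
    }, 0),
    xml2::xml_attr(comps, "id"))
  sizes <- unique(round(comp_size, 12))
  if (length(sizes) > 1)
    stop("compartments with differing sizes are not supported (", path, ")")
  volume <- if (length(sizes)) sizes[[1]] else 1

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true" |
    xml2::xml_attr(sp_nodes, "constant") %in% "true"
  sp_init <- vapply(sp_nodes, function(s) {
    v <- xml_num_attr(s, "initialConcentration", "initialAmount")
    if (is.na(v)) 0 else v
  }, 0)
  names(sp_init) <- sp_id
  dynamic <- sp_id[!sp_boundary]

  params <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  env <- stats::setNames(vapply(params, function(p) xml_num_attr(p, "value"), 0),
                         xml2::xml_attr(params, "id"))
  env <- c(env[!is.na(env)], comp_size, sp_init[sp_boundary])
  env[names(rule_vals)] <- rule_vals

  reactions <- list()
  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id") %||% "reaction"
    read_side <- function(xp) {
      refs <- xml2::xml_find_all(rx, xp)
      out <- stats::setNames(integer(), character())
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml_num_attr(ref, "stoichiometry")
        if (is.na(st)) st <- 1
        if (!is_wholenumber(st))
          nonpolynomial_error(rid, "non-integer stoichiometry")
        if (sp %in% dynamic)
          out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + as.integer(round(st))
      }
      out
    }
    lhs <- read_side("./listOfReactants/speciesReference")
    rhs <- read_side("./listOfProducts/speciesReference")

    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      nonpolynomial_error(rid, "missing kinetic law")
    locals <- xml2::xml_find_all(
      kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")
    lenv <- env
    if (length(locals))
      lenv[xml2::xml_attr(locals, "id")] <-
        vapply(locals, function(p) xml_num_attr(p, "value"), 0)
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing"))
      nonpolynomial_error(rid, "missing math element")
    if (length(bad_rule_targets)) {
      refd <- trimws(xml2::xml_text(xml2::xml_find_all(math, ".//ci")))
      hit <- intersect(refd, bad_rule_targets)
      if (length(hit))
        nonpolynomial_error(rid, paste0("symbol '", hit[[1]],
                                        "' is set by a non-constant rule"))
    }
    poly <- mathml_poly(math, lenv, dynamic, rid)
    net <- stats::setNames(integer(), character())
    for (sp in union(names(lhs), names(rhs)))
      net[sp] <- (if (sp %in% names(rhs)) rhs[[sp]] else 0L) -
        (if (sp %in% names(lhs)) lhs[[sp]] else 0L)
    for (term in unclass(poly)) {
      coef <- term$coef / volume
      if (coef == 0) next
      flip <- coef < 0
      this_net <- if (flip) -net else net
      reactions[[length(reactions) + 1L]] <- reaction(
        reactants = stats::setNames(pmax(-this_net, 0L), names(this_net)),
        products = stats::setNames(pmax(this_net, 0L), names(this_net)),
        k = abs(coef), exponents = term$exp,
        id = paste0(rid, if (length(poly) > 1 || flip)
          paste0("_t", length(reactions) + 1L) else ""))
    }
  }
  reaction_network(dynamic, reactions, sp_init[dynamic])
}
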