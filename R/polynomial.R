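#' Integer order of a positive quantity
#'
#' Orders encode magnitudes on the scale of a small parameter
#' \eqn{\epsilon}: a quantity \eqn{k \approx \epsilon^\gamma} has order
#' \eqn{\gamma = \mathrm{round}(\log k / \log \epsilon)}.  Larger orders
#' mean smaller quantities.  Ties (exact half-integers) round away from
#' zero; this rule is centralized here.  With `q > 1`, rational orders with
#' common denominator `q` are supported by working on the pre-multiplied
#' integer scale \eqn{\mathrm{round}(q\,\log k/\log\epsilon)}.
#'
#' @param k positive numeric (vectorized).
#' @param epsilon small parameter in (0, 1).
#' @param q common denominator pre-multiplier (default 1).
#' @return integer order(s).
#' @examples
#' parameter_order(0.001, 0.1)  # 3
#' parameter_order(2e4, 0.1)    # -4
#' @export
parameter_order <- function(k, epsilon = 0.1, q = 1L) {
  if (any(k <= 0)) stop("parameter_order requires k > 0")
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  x <- q * log(k) / log(epsilon)
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

## Canonical monomial identity label: sign then exponents, e.g. "-x1*x2^2".
## Magnitudes are deliberately not part of the identity.
monomial_label <- function(m) {
  if (!length(m$exponents)) return(paste0(ifelse(m$sign > 0, "+", "-"), "1"))
  e <- m$exponents[order(names(m$exponents))]
  paste0(ifelse(m$sign > 0, "+", "-"),
         paste(ifelse(e == 1L, names(e), paste0(names(e), "^", e)), collapse = "*"))
}

## components: the individual signed coefficients merged into this
## monomial, each with its own order; truncation uses them to discard
## dominated parts of a merged coefficient (e.g. the k2 part of
## (k-1 + k2) x2 when k2 is of higher order than k-1).
new_monomial <- function(sign, magnitude, gamma, exponents, components = NULL) {
  stopifnot(magnitude > 0, sign %in% c(-1, 1))
  exponents <- exponents[exponents > 0]
  list(sign = as.integer(sign), magnitude = magnitude,
       gamma = as.integer(gamma),
       exponents = stats::setNames(as.integer(exponents), names(exponents)),
       components = components %||%
         list(list(magnitude = magnitude, gamma = as.integer(gamma))))
}

#' Degree of a monomial at an order vector
#'
#' The \eqn{\epsilon}-order of a rate monomial at concentration orders `a`
#' is \eqn{\mu = \gamma + \langle a, \alpha \rangle}; it is affine in `a`.
#'
#' @param m a monomial (element of a [polynomial_system()] equation).
#' @param a named integer vector of species orders covering the monomial's
#'   exponents.
#' @return integer degree.
#' @export
monomial_degree <- function(m, a) {
  need <- names(m$exponents)
  if (!all(need %in% names(a)))
    stop("missing species order(s): ", paste(setdiff(need, names(a)), collapse = ", "))
  as.integer(m$gamma + sum(a[need] * m$exponents))
}

#' Build the signed-monomial ODE system of a network
#'
#' Converts a mass-action network into the polynomial right-hand sides
#' \eqn{dx_i/dt = \sum_j k_j S_{ij} x^{\alpha_j}}.  Within one equation,
#' monomials with identical sign and exponent vector are merged by summing
#' magnitudes; a positive/negative pair with equal exponents cancels
#' magnitudes (keeping the dominant sign, dropping the monomial on exact
#' cancellation).  Coefficient orders \eqn{\gamma} are computed on the
#' merged magnitudes via [parameter_order()].  Species with empty equations
#' are flagged inert and take no part in equilibration.
#'
#' @param network a [reaction_network()].
#' @param epsilon small parameter in (0, 1); default 0.1.
#' @param q order denominator pre-multiplier, see [parameter_order()].
#' @return an object of class `polynomial_system` with one monomial list
#'   per species, the stoichiometric matrix, `epsilon`, and the orders of
#'   nonzero initial concentrations.
#' @export
build_odes <- function(network, epsilon = 0.1, q = 1L) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  contrib <- stats::setNames(vector("list", n_species(network)), network$species)
  for (r in network$reactions) {
    alpha <- r$exponents %||% r$reactants
    for (sp in union(names(r$reactants), names(r$products))) {
      Sij <- (if (sp %in% names(r$products)) r$products[[sp]] else 0L) -
        (if (sp %in% names(r$reactants)) r$reactants[[sp]] else 0L)
      if (Sij == 0L) next
      contrib[[sp]] <- c(contrib[[sp]],
                         list(list(coef = r$k * Sij, exponents = alpha)))
    }
  }
  equations <- lapply(contrib, function(terms) {
    if (!length(terms)) return(list())
    keys <- vapply(terms, function(t) p_key(t$exponents), "")
    merged <- list()
    for (k in unique(keys)) {
      coefs <- vapply(terms[keys == k], `[[`, 0, "coef")
      coef <- sum(coefs)
      if (abs(coef) < 1e-300) next   # exact cancellation
      e <- terms[keys == k][[1]]$exponents
      ## component orders are meaningful only when no cancellation occurred
      comps <- if (all(sign(coefs) == sign(coef)))
        lapply(abs(coefs), function(m)
          list(magnitude = m, gamma = parameter_order(m, epsilon, q)))
      merged[[length(merged) + 1L]] <-
        new_monomial(sign(coef), abs(coef),
                     parameter_order(abs(coef), epsilon, q), e, comps)
    }
    merged[order(vapply(merged, monomial_label, ""), method = "radix")]
  })
  inert <- names(equations)[vapply(equations, length, 0L) == 0]
  init_orders <- stats::setNames(rep(NA_integer_, n_species(network)), network$species)
  pos <- network$init > 0
  init_orders[pos] <- parameter_order(network$init[pos], epsilon, q)
  structure(list(species = network$species, equations = equations,
                 stoichiometric_matrix = stoichiometric_matrix(network),
                 epsilon = epsilon, q = as.integer(q),
                 initial_orders = init_orders, inert = inert,
                 network = network),
            class = "polynomial_system")
}

#' @rdname build_odes
#' @param species,equations,... used by the low-level constructor
#'   `polynomial_system()` for systems not derived from a network
#'   (e.g. fixtures built directly from equations).
#' @param epsilon small parameter in (0, 1).
#' @param stoichiometric_matrix optional integer matrix (species x reactions).
#' @param initial_orders optional named integer vector.
#' @export
polynomial_system <- function(species, equations, epsilon = 0.1,
                              stoichiometric_matrix = NULL,
                              initial_orders = NULL, ...) {
  stopifnot(length(equations) == length(species))
  names(equations) <- species
  inert <- species[vapply(equations, length, 0L) == 0]
  structure(list(species = species, equations = equations,
                 stoichiometric_matrix = stoichiometric_matrix,
                 epsilon = epsilon, q = 1L,
                 initial_orders = initial_orders, inert = inert, ...),
            class = "polynomial_system")
}

## Signed species-by-monomial coefficient matrix: one column per distinct
## monomial x^alpha (identity ignores sign), entries sum(sign * magnitude).
monomial_matrix <- function(system, equations = system$equations) {
  keys <- unique(unlist(lapply(equations, function(eq)
    vapply(eq, function(m) p_key(m$exponents), ""))))
  M <- matrix(0, length(system$species), length(keys),
              dimnames = list(system$species, keys))
  for (sp in names(equations))
    for (m in equations[[sp]])
      M[sp, p_key(m$exponents)] <- M[sp, p_key(m$exponents)] + m$sign * m$magnitude
  M
}

format_monomial <- function(m, digits = 4) {
  coef <- signif(m$magnitude, digits)
  e <- m$exponents
  xs <- if (length(e))
    paste(ifelse(e == 1L, names(e), paste0(names(e), "^", e)), collapse = "*")
  else ""
  body <- if (!nzchar(xs)) as.character(coef)
  else if (coef == 1) xs else paste0(coef, "*", xs)
  paste0(ifelse(m$sign > 0, "+", "-"), body)
}

format_equation <- function(monomials, digits = 4) {
  if (!length(monomials)) return("0")
  paste(vapply(monomials, format_monomial, "", digits = digits), collapse = " ")
}

#' @export
print.polynomial_system <- function(x, ...) {
  cat(sprintf("Polynomial ODE system (%d species, epsilon = %g)\n",
              length(x$species), x$epsilon))
  for (sp in x$species)
    cat(sprintf("  d%s/dt = %s\n", sp, format_equation(x$equations[[sp]])))
  if (length(x$inert)) cat("  inert species:", paste(x$inert, collapse = ", "), "\n")
  invisible(x)
}
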