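#' Tropically truncated system at an equilibration
#'
#' Keeps, in each equation, exactly the monomials whose degree attains the
#' equation's minimal degree at the given orders (all dominated monomials
#' are eliminated), and records the timescale exponent
#' \eqn{\mu_{i,\min} - a_i} of each species: in the rescaled equations
#' \eqn{d\bar x_i/dt = \epsilon^{\mu_j - a_i}\,\bar k_j S_{ij} \bar x^{\alpha_j}},
#' a smaller exponent means a faster variable.
#'
#' A retained monomial whose merged coefficient combines contributions of
#' different orders (such as \eqn{(k_{-1} + k_2) x_2}) keeps only its
#' minimal-order components; the dominated part of the coefficient joins
#' the dropped terms.  Truncation is idempotent: truncating a
#' `truncated_system` at the same orders changes nothing.
#'
#' @param system a [polynomial_system()] or a `truncated_system`.
#' @param eq an `equilibration` (from [classify_solution()]) or a named
#'   integer order vector covering all species.
#' @return an object of class `truncated_system` with fields `base`,
#'   `orders`, `retained` (dominant monomials per species), `dropped`
#'   (dominated monomials per species) and `timescale_exponents`.
#' @export
truncate_system <- function(system, eq) {
  if (inherits(system, "truncated_system"))
    system <- polynomial_system(system$base$species, system$retained,
                                epsilon = system$base$epsilon,
                                initial_orders = system$base$initial_orders)
  orders <- if (inherits(eq, "equilibration")) eq$orders else eq
  if (!all(setdiff(system$species, system$inert) %in% names(orders)))
    stop("orders must cover all non-inert species")
  retained <- dropped <- stats::setNames(vector("list", length(system$species)),
                                         system$species)
  exponents <- stats::setNames(rep(NA_integer_, length(system$species)),
                               system$species)
  epsilon <- system$epsilon; q <- system$q %||% 1L
  for (sp in system$species) {
    mons <- system$equations[[sp]]
    if (!length(mons)) { retained[[sp]] <- dropped[[sp]] <- list(); next }
    d <- vapply(mons, monomial_degree, 0L, a = orders)
    mn <- min(d)
    keep <- list(); drop <- mons[d > mn]
    for (m in mons[d == mn]) {
      ## a merged coefficient may itself contain dominated parts: keep only
      ## its minimal-order components, the rest joins the dropped terms
      gammas <- vapply(m$components, `[[`, 0L, "gamma")
      gmin <- min(gammas)
      if (any(gammas > gmin)) {
        keep_mag <- sum(vapply(m$components[gammas == gmin], `[[`, 0, "magnitude"))
        drop_mag <- sum(vapply(m$components[gammas > gmin], `[[`, 0, "magnitude"))
        keep[[length(keep) + 1L]] <-
          new_monomial(m$sign, keep_mag, parameter_order(keep_mag, epsilon, q),
                       m$exponents, m$components[gammas == gmin])
        drop[[length(drop) + 1L]] <-
          new_monomial(m$sign, drop_mag, parameter_order(drop_mag, epsilon, q),
                       m$exponents, m$components[gammas > gmin])
      } else keep[[length(keep) + 1L]] <- m
    }
    retained[[sp]] <- keep
    dropped[[sp]] <- drop
    exponents[sp] <- mn - orders[[sp]]
  }
  structure(list(base = system, orders = orders, retained = retained,
                 dropped = dropped, timescale_exponents = exponents),
            class = "truncated_system")
}

#' Order variables by timescale
#'
#' Ascending timescale exponent \eqn{\mu_{i,\min} - a_i}: fastest variables
#' first, ties grouped at equal exponent.  Inert species (no monomials)
#' are omitted.
#'
#' @param trunc a [truncate_system()] result.
#' @return data frame with columns `species` and `exponent`, fastest first.
#' @export
order_timescales <- function(trunc) {
  e <- trunc$timescale_exponents
  e <- e[!is.na(e)]
  out <- data.frame(species = names(e), exponent = as.integer(e),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$exponent, out$species), , drop = FALSE]
}

#' Conserved pools of the truncated dynamics
#'
#' Finds semi-positive integer vectors \eqn{b} annihilating the truncated
#' system's species-by-monomial coefficient matrix but not the full
#' system's: linear combinations \eqn{z = \sum b_i x_i} conserved by the
#' fast (dominant) dynamics only.  Such pools are supplementary slow
#' variables; each is reported with its residual driving monomials, the
#' signed sum \eqn{\sum_i b_i \cdot (\text{dropped monomials of equation } i)}
#' of previously dominated terms, which is the pool's slow derivative.
#'
#' @param trunc a [truncate_system()] result.
#' @return list of pools, each `list(coefficients, driving, driving_orders)`
#'   where `driving` is a list of monomials and `driving_orders` their
#'   degrees at the truncation's order vector.
#' @export
find_new_pools <- function(trunc) {
  Ct <- monomial_matrix(trunc$base, trunc$retained)
  Cf <- monomial_matrix(trunc$base)
  cand <- find_invariants(Ct)
  full_zero <- function(b) all(abs(as.vector(b %*% Cf[names(b), , drop = FALSE])) < 1e-9)
  pools <- list()
  for (b in cand) {
    if (full_zero(b)) next   # conserved by the full system too: not a pool
    driving <- list()
    for (sp in names(b)[b > 0])
      for (m in trunc$dropped[[sp]])
        driving <- c(driving, list(list(sign = m$sign, coef = b[[sp]] * m$magnitude,
                                        exponents = m$exponents)))
    ## merge signed contributions per monomial, allowing cancellation
    keys <- vapply(driving, function(t) p_key(t$exponents), "")
    merged <- list()
    for (k in unique(keys)) {
      tot <- sum(vapply(driving[keys == k], function(t) t$sign * t$coef, 0))
      if (abs(tot) < 1e-12) next
      e <- driving[keys == k][[1]]$exponents
      merged[[length(merged) + 1L]] <-
        new_monomial(sign(tot), abs(tot),
                     parameter_order(abs(tot), trunc$base$epsilon, trunc$base$q), e)
    }
    merged <- merged[order(vapply(merged, monomial_label, ""), method = "radix")]
    pools[[length(pools) + 1L]] <- list(
      coefficients = b[b > 0],
      driving = merged,
      driving_orders = vapply(merged, monomial_degree, 0L, a = trunc$orders))
  }
  pools
}

#' @export
print.truncated_system <- function(x, ...) {
  cat("Tropically truncated system at orders",
      paste(names(x$orders), x$orders, sep = "=", collapse = ", "), "\n")
  for (sp in x$base$species) {
    if (!length(x$base$equations[[sp]])) next
    cat(sprintf("  d%s/dt = %s   [exponent %d]\n", sp,
                format_equation(x$retained[[sp]]), x$timescale_exponents[[sp]]))
  }
  invisible(x)
}

## JSON-able description of a truncated system
truncation_record <- function(trunc, pools = NULL) {
  list(orders = as.list(trunc$orders),
       retained = lapply(trunc$retained, function(ms)
         vapply(ms, monomial_label, "")),
       timescale_exponents = as.list(
         trunc$timescale_exponents[!is.na(trunc$timescale_exponents)]),
       pools = lapply(pools %||% find_new_pools(trunc), function(p)
         list(coefficients = as.list(p$coefficients),
              driving = vapply(p$driving, monomial_label, ""))))
}
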