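## Independent brute-force oracles, written against the data structures
## only (plain loops, no solver code paths).

## Degree of one monomial at integer orders `a` (named).
oracle_degree <- function(m, a) m$gamma + sum(m$exponents * a[names(m$exponents)])

## All integer points of [-D, D]^n satisfying the equilibration condition
## (positive-side minimum equals negative-side minimum) for each species in
## `species` (default: every two-signed equation), plus every
## conservation-law minimum constraint.  Returns a sorted matrix.
oracle_solutions <- function(system, laws = list(), D = 6, species = NULL) {
  referenced <- unique(c(
    unlist(lapply(system$equations, function(eq)
      lapply(eq, function(m) names(m$exponents)))),
    unlist(lapply(laws, function(l) names(l$coefficients)))))
  vars <- system$species[!(system$species %in% system$inert) |
                           system$species %in% referenced]
  grid <- as.matrix(expand.grid(rep(list(-D:D), length(vars))))
  colnames(grid) <- vars
  if (is.null(species)) {
    species <- vars[vapply(vars, function(sp) {
      sg <- vapply(system$equations[[sp]], `[[`, 0L, "sign")
      any(sg > 0) && any(sg < 0)
    }, TRUE)]
  }
  hits <- logical(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    ok <- TRUE
    for (sp in species) {
      pos <- Inf; neg <- Inf
      for (m in system$equations[[sp]]) {
        d <- oracle_degree(m, a)
        if (m$sign > 0) pos <- min(pos, d) else neg <- min(neg, d)
      }
      if (pos != neg) { ok <- FALSE; break }
    }
    if (ok) for (l in laws) {
      mem <- names(l$coefficients)
      degs <- vapply(mem, function(sp)
        parameter_order(l$coefficients[[sp]], system$epsilon) + a[[sp]], 0)
      if (min(degs) != l$kappa) { ok <- FALSE; break }
    }
    hits[r] <- ok
  }
  sols <- grid[hits, , drop = FALSE]
  storage.mode(sols) <- "integer"
  if (nrow(sols) > 1)
    sols <- sols[do.call(order, as.data.frame(sols)), , drop = FALSE]
  rownames(sols) <- NULL
  sols
}

## Exhaustive semi-positive left-kernel vectors with entries in 0..bound,
## gcd-reduced, unique, restricted to minimal supports.
oracle_invariants <- function(S, bound = 3) {
  n <- nrow(S)
  grid <- as.matrix(expand.grid(rep(list(0:bound), n)))
  found <- list()
  for (r in seq_len(nrow(grid))) {
    b <- grid[r, ]
    if (!any(b > 0)) next
    if (any(abs(as.vector(b %*% S)) > 1e-9)) next
    g <- Reduce(function(x, y) if (y == 0) x else {
      a <- x; bb <- y
      while (bb > 0) { t <- a %% bb; a <- bb; bb <- t }
      a
    }, b[b > 0])
    b <- b / g
    found[[paste(b, collapse = ",")]] <- stats::setNames(as.integer(b), rownames(S))
  }
  found <- unname(found)
  if (!length(found)) return(list())
  supports <- lapply(found, function(b) which(b > 0))
  minimal <- vapply(seq_along(found), function(i)
    !any(vapply(seq_along(found), function(j)
      i != j && all(supports[[j]] %in% supports[[i]]) &&
        length(supports[[j]]) < length(supports[[i]]), TRUE)), TRUE)
  found <- found[minimal]
  found[order(vapply(found, paste, "", collapse = ","))]
}

## Two-signed species of a system (those carrying an equilibration
## constraint).
equilibratable_species <- function(system) {
  vars <- setdiff(system$species, system$inert)
  vars[vapply(vars, function(sp) {
    sg <- vapply(system$equations[[sp]], `[[`, 0L, "sign")
    any(sg > 0) && any(sg < 0)
  }, TRUE)]
}

## Frozen branch-defining parameter regimes for the Michaelis-Menten
## fixtures used across the tests: gamma1, gamma_rev, gamma2, gamma_e.
mm_regime_slow_product <- c(gamma1 = 0, gamma_rev = 0, gamma2 = 1, gamma_e = 1)
mm_regime_fast_product <- c(gamma1 = 0, gamma_rev = 2, gamma2 = 0, gamma_e = 1)

## Labels of retained monomials of a truncated system, per species.
retained_labels <- function(trunc) {
  lapply(trunc$retained, function(ms)
    sort(vapply(ms, tropicaleq:::monomial_label, ""), method = "radix"))
}
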