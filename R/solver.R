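#' Encode tropical equilibration as a finite-domain constraint problem
#'
#' Builds the constraint problem over one integer order variable \eqn{a_i}
#' per non-inert species.  For each equilibrated species, a shared minimum
#' variable \eqn{M_i} links the positive-side and negative-side
#' minimum-with-count constraints, so that the minimal degree among
#' positive monomials equals the minimal degree among negative monomials.
#' Each conservation law contributes the constraint that the minimum of its
#' member degrees equals the law's constant order \eqn{\kappa}.  Species
#' whose equations are empty (inert) or single-signed cannot equilibrate
#' and are excluded from equilibration constraints (they keep their order
#' variables, which conservation laws may still constrain).
#'
#' @param system a [polynomial_system()].
#' @param laws list of `conservation_law` objects (see [attach_constants()]).
#' @param min_count total required multiplicity of each equation's overall
#'   minimum; the default 2 is implied by the shared-minimum encoding (one
#'   positive plus one negative attaining monomial) and values above 2 add
#'   an explicit count constraint over the combined monomial list.
#' @param domain initial symmetric domain half-width D (orders in [-D, D]).
#' @param species optional subset of species whose equations must
#'   equilibrate; defaults to all equilibratable (two-signed) species.
#'   Passing a subset yields partial equilibrations.
#' @return an object of class `tropical_problem`.
#' @export
build_problem <- function(system, laws = list(), min_count = 2L, domain = 2L,
                          species = NULL) {
  stopifnot(inherits(system, "polynomial_system"), min_count >= 1, domain >= 1)
  eqs <- system$equations
  order_species <- order_variable_species(system, laws)
  var_of <- stats::setNames(seq_along(order_species), order_species)

  signs <- lapply(eqs, function(eq) vapply(eq, `[[`, 0L, "sign"))
  equilibratable <- order_species[vapply(order_species, function(sp)
    any(signs[[sp]] > 0) && any(signs[[sp]] < 0), TRUE)]
  excluded <- lapply(setdiff(system$species, equilibratable), function(sp)
    list(species = sp,
         reason = if (sp %in% system$inert) "inert (empty equation)"
                  else "single-signed equation"))
  names(excluded) <- vapply(excluded, `[[`, "", "species")

  target <- species %||% equilibratable
  if (!all(target %in% equilibratable))
    stop("cannot equilibrate: ",
         paste(setdiff(target, equilibratable), collapse = ", "))
  if (!length(target))
    stop(structure(class = c("tropicaleq_nothing_to_equilibrate",
                             "error", "condition"),
                   list(message = "nothing to equilibrate: every species has a single-signed or empty equation",
                        call = NULL)))

  nv <- length(order_species)
  m_of <- stats::setNames(nv + seq_along(target), target)
  mono_form <- function(m) fd_form(m$gamma, var_of[names(m$exponents)],
                                   m$exponents)
  constraints <- list()
  for (sp in target) {
    eq <- eqs[[sp]]
    sgn <- signs[[sp]]
    pos <- lapply(eq[sgn > 0], mono_form)
    neg <- lapply(eq[sgn < 0], mono_form)
    mv <- list(var = m_of[[sp]])
    constraints <- c(constraints,
                     list(min_with_count(pos, mv, 1L),
                          min_with_count(neg, mv, 1L)))
    if (min_count > 2)
      constraints <- c(constraints,
                       list(min_with_count(c(pos, neg), mv, min_count)))
  }
  for (l in laws) {
    b <- l$coefficients
    members <- intersect(names(b), order_species)
    if (!length(members)) next
    forms <- lapply(members, function(sp)
      fd_form(parameter_order(b[[sp]], system$epsilon, system$q),
              var_of[[sp]], 1L))
    constraints <- c(constraints,
                     list(min_with_count(forms, list(const = l$kappa), 1L)))
  }
  structure(list(system = system, laws = laws,
                 order_species = order_species, var_of = var_of, m_of = m_of,
                 constraints = constraints, target = target,
                 excluded = excluded, min_count = as.integer(min_count),
                 domain = as.integer(domain)),
            class = "tropical_problem")
}

## Species needing an order variable: non-inert ones, plus any species an
## equation's monomials or a conservation law refer to (an inert catalyst
## still rescales other equations).
order_variable_species <- function(system, laws = list()) {
  referenced <- unique(c(
    unlist(lapply(system$equations, function(eq)
      lapply(eq, function(m) names(m$exponents)))),
    unlist(lapply(laws, function(l) names(l$coefficients)))))
  system$species[!(system$species %in% system$inert) |
                   system$species %in% referenced]
}

#' @export
print.tropical_problem <- function(x, ...) {
  cat(sprintf("Tropical equilibration problem: %d order variables, %d constraints, domain [-%d, %d]\n",
              length(x$order_species), length(x$constraints), x$domain, x$domain))
  cat("  equilibrated species:", paste(x$target, collapse = ", "), "\n")
  if (length(x$excluded))
    cat("  excluded:", paste(vapply(x$excluded, function(e)
      sprintf("%s (%s)", e$species, e$reason), ""), collapse = "; "), "\n")
  invisible(x)
}

## Direct verification of an order vector against a problem (independent of
## the propagation path): Eq-style min comparisons plus law minima.
verify_orders <- function(problem, a) {
  sys <- problem$system
  for (sp in problem$target) {
    d <- vapply(sys$equations[[sp]], monomial_degree, 0L, a = a)
    sg <- vapply(sys$equations[[sp]], `[[`, 0L, "sign")
    if (min(d[sg > 0]) != min(d[sg < 0])) return(FALSE)
    if (problem$min_count > 2 && sum(d == min(d)) < problem$min_count) return(FALSE)
  }
  for (l in problem$laws) {
    b <- l$coefficients
    members <- intersect(names(b), names(a))
    if (!length(members)) next
    degs <- parameter_order(b[members], sys$epsilon, sys$q) + a[members]
    if (min(degs) != l$kappa) return(FALSE)
  }
  TRUE
}

#' Enumerate all tropical equilibrations in a box
#'
#' Complete enumeration of the integer order vectors in \eqn{[-D, D]^n}
#' satisfying the problem's equilibration and conservation constraints.
#' Search interleaves bounds propagation of the reified minimum constraints
#' with dichotomic bisection of the variable domains (no variable-selection
#' heuristic); every candidate is re-verified by direct degree evaluation
#' before being reported.
#'
#' @param problem a [build_problem()] result.
#' @param solution_cap stop (and flag `truncated`) after this many
#'   solutions; under-constrained systems can have solution counts growing
#'   without bound as the box grows, and a hit cap together with
#'   `boundary_hit` is the practical detector of such an infinity.
#' @param domain optional override of the problem's domain half-width.
#' @return an object of class `tropical_solutions`: a list with `orders`
#'   (matrix, one row per solution), `solutions` (list of classified
#'   [classify_solution()] results), `domain_used`, `boundary_hit`,
#'   `truncated` and `excluded_variables`.
#' @export
solve_all <- function(problem, solution_cap = 1e6, domain = NULL) {
  D <- as.integer(domain %||% problem$domain)
  nv <- length(problem$order_species)
  nm <- length(problem$m_of)
  state <- list(lo = c(rep(-D, nv), rep(-Inf, nm)),
                hi = c(rep(D, nv), rep(Inf, nm)))
  ## M bounds derived from the forms they cap
  for (cn in problem$constraints)
    if (!is.null(cn$m$var)) {
      state$lo[cn$m$var] <- max(state$lo[cn$m$var],
                                min(vapply(cn$forms, form_lo, 0, lo = state$lo)))
      state$hi[cn$m$var] <- min(state$hi[cn$m$var],
                                min(vapply(cn$forms, form_hi, 0, hi = state$hi)))
    }
  constrained <- sort(unique(unlist(lapply(problem$constraints, function(cn)
    unlist(lapply(cn$forms, `[[`, "idx"))))))
  branch_vars <- intersect(seq_len(nv), constrained)
  free_vars <- setdiff(seq_len(nv), branch_vars)

  acc <- new.env(parent = emptyenv())
  acc$rows <- list(); acc$truncated <- FALSE
  emit <- function(a) {
    orders <- stats::setNames(as.integer(a[seq_len(nv)]), problem$order_species)
    if (!verify_orders(problem, orders)) return(TRUE)
    acc$rows[[length(acc$rows) + 1L]] <- orders
    if (length(acc$rows) >= solution_cap) { acc$truncated <- TRUE; FALSE } else TRUE
  }
  fd_enumerate(problem$constraints, state, branch_vars, free_vars, emit)

  orders <- if (length(acc$rows)) do.call(rbind, acc$rows)
  else matrix(integer(), 0, nv, dimnames = list(NULL, problem$order_species))
  orders <- unique(orders)
  if (nrow(orders) > 1)
    orders <- orders[do.call(order, as.data.frame(orders)), , drop = FALSE]
  structure(list(
    orders = orders,
    solutions = lapply(seq_len(nrow(orders)), function(i)
      classify_solution(problem$system, orders[i, ])),
    domain_used = D,
    boundary_hit = nrow(orders) > 0 && any(abs(orders) == D),
    truncated = acc$truncated,
    excluded_variables = names(problem$excluded),
    problem = problem),
    class = "tropical_solutions")
}

#' Solve with iterative domain expansion
#'
#' Tries the problem on the initial domain (default \eqn{[-2, 2]}); when no
#' solution exists there, the half-width doubles (4, 8, ...) until a
#' domain yields solutions or `max_domain` (default 128, i.e. magnitudes
#' between \eqn{\epsilon^{128}} and \eqn{\epsilon^{-128}}) is exhausted.
#' Solutions found at half-width D remain solutions at 2D (monotonicity),
#' so the first non-failing domain is returned.
#'
#' @inheritParams solve_all
#' @param max_domain final half-width of the expansion schedule.
#' @return a `tropical_solutions` object; `domain_used` records the final
#'   half-width (equal to `max_domain` when no solution was found at all).
#' @export
solve_with_expansion <- function(problem, solution_cap = 1e6,
                                 max_domain = 128L) {
  D <- max(1L, as.integer(problem$domain))
  repeat {
    sol <- solve_all(problem, solution_cap, domain = D)
    if (nrow(sol$orders) > 0 || D >= max_domain) return(sol)
    D <- min(2L * D, as.integer(max_domain))
  }
}

#' Classify an order vector
#'
#' Computes, for every species, the minimal degree of its equation at the
#' given orders, the monomials attaining that minimum, and whether the
#' positive- and negative-side minima coincide (the species is then
#' equilibrated).
#'
#' @param system a [polynomial_system()].
#' @param orders named integer vector covering all species of the system.
#' @return an object of class `equilibration` with fields `orders`,
#'   `achieved_minimum`, `active_monomials` (labels of minimal monomials),
#'   and `equilibrated`.
#' @export
classify_solution <- function(system, orders) {
  equil <- character()
  achieved <- stats::setNames(rep(NA_integer_, length(system$species)),
                              system$species)
  active <- stats::setNames(vector("list", length(system$species)),
                            system$species)
  for (sp in system$species) {
    eq <- system$equations[[sp]]
    if (!length(eq)) { active[[sp]] <- character(); next }
    d <- vapply(eq, monomial_degree, 0L, a = orders)
    sg <- vapply(eq, `[[`, 0L, "sign")
    mn <- min(d)
    achieved[sp] <- mn
    act <- d == mn
    active[[sp]] <- sort(vapply(eq[act], monomial_label, ""), method = "radix")
    if (any(sg[act] > 0) && any(sg[act] < 0)) equil <- c(equil, sp)
  }
  structure(list(orders = orders, achieved_minimum = achieved,
                 active_monomials = active, equilibrated = equil),
            class = "equilibration")
}

#' @export
print.equilibration <- function(x, ...) {
  cat("orders:", paste(names(x$orders), x$orders, sep = "=", collapse = ", "), "\n")
  cat("equilibrated:", if (length(x$equilibrated))
    paste(x$equilibrated, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' @export
print.tropical_solutions <- function(x, ...) {
  cat(sprintf("Tropical equilibrations: %d solution(s) in [-%d, %d]^%d\n",
              nrow(x$orders), x$domain_used, x$domain_used, ncol(x$orders)))
  if (x$truncated) cat("  [solution cap reached: enumeration truncated]\n")
  if (x$boundary_hit) cat("  [solutions touch the domain boundary]\n")
  if (length(x$excluded_variables))
    cat("  excluded variables:", paste(x$excluded_variables, collapse = ", "), "\n")
  invisible(x)
}

## ---- branch grouping ----

law_active_members <- function(laws, system, orders) {
  lapply(laws, function(l) {
    b <- l$coefficients
    members <- intersect(names(b), names(orders))
    degs <- parameter_order(b[members], system$epsilon, system$q) + orders[members]
    sort(members[degs == min(degs)], method = "radix")
  })
}

branch_signature <- function(cl, law_act) {
  paste(paste(sort(cl$equilibrated, method = "radix"), collapse = ","),
        paste(vapply(names(cl$active_monomials), function(sp)
          paste0(sp, ":", paste(cl$active_monomials[[sp]], collapse = ",")), ""),
          collapse = "|"),
        paste(vapply(law_act, paste, "", collapse = ","), collapse = "|"),
        sep = " || ")
}

sig_dominates <- function(a, b) {
  ## TRUE when signature a is componentwise a superset of signature b
  if (!all(b$equilibrated %in% a$equilibrated)) return(FALSE)
  for (sp in names(a$active)) if (!all(b$active[[sp]] %in% a$active[[sp]]))
    return(FALSE)
  if (length(a$law_act))
    for (i in seq_along(a$law_act))
      if (!all(b$law_act[[i]] %in% a$law_act[[i]])) return(FALSE)
  TRUE
}

#' Group equilibrations into branches
#'
#' Partitions a solution set by signature: the set of equilibrated
#' species, the per-equation active (minimal-degree) monomials, and the
#' active members of each conservation law.  Junction points where tropical
#' half-lines meet carry strictly larger active sets than their neighbours;
#' such vertex classes are merged into an adjacent branch whose signature
#' they dominate, so each branch corresponds to one maximal family of
#' order vectors sharing the same dominance structure (a segment or
#' half-line in order space).
#'
#' @param solutions a `tropical_solutions` object, or a matrix of order
#'   vectors (one row per solution).
#' @param system the [polynomial_system()] (defaults to the one stored in
#'   `solutions`).
#' @param laws conservation laws used in the signature (defaults to those
#'   stored in `solutions`).
#' @return list of class `tropical_branches`; each branch has `signature`,
#'   `equilibrated`, `active_monomials`, `law_active`, `representative`
#'   (an order vector), `n_points`, and `points` (matrix of member order
#'   vectors).
#' @export
group_branches <- function(solutions, system = NULL, laws = NULL) {
  if (inherits(solutions, "tropical_solutions")) {
    system <- system %||% solutions$problem$system
    laws <- laws %||% solutions$problem$laws
    orders <- solutions$orders
  } else orders <- solutions
  if (!nrow(orders)) return(structure(list(), class = "tropical_branches"))
  laws <- laws %||% list()

  classes <- list()
  for (i in seq_len(nrow(orders))) {
    a <- orders[i, ]
    cl <- classify_solution(system, a)
    law_act <- law_active_members(laws, system, a)
    key <- branch_signature(cl, law_act)
    if (is.null(classes[[key]]))
      classes[[key]] <- list(signature = key,
                             equilibrated = sort(cl$equilibrated, method = "radix"),
                             active = cl$active_monomials,
                             law_act = law_act,
                             points = list())
    classes[[key]]$points[[length(classes[[key]]$points) + 1L]] <- a
  }
  keys <- sort(names(classes), method = "radix")
  absorbed_into <- stats::setNames(rep(NA_character_, length(keys)), keys)
  for (k in keys) {
    for (k2 in keys) {
      if (k == k2) next
      if (sig_dominates(classes[[k]], classes[[k2]])) {
        absorbed_into[k] <- k2
        break   # deterministic: first dominated class in sorted order
      }
    }
  }
  ## follow absorption chains to a non-absorbed root
  root_of <- function(k) {
    seen <- character()
    while (!is.na(absorbed_into[[k]]) && !(k %in% seen)) {
      seen <- c(seen, k); k <- absorbed_into[[k]]
    }
    k
  }
  out <- list()
  for (k in keys) {
    r <- root_of(k)
    if (is.null(out[[r]])) {
      out[[r]] <- classes[[r]]
      out[[r]]$points <- list()
    }
    out[[r]]$points <- c(out[[r]]$points, classes[[k]]$points)
  }
  branches <- lapply(out, function(b) {
    pts <- do.call(rbind, b$points)
    list(signature = b$signature, equilibrated = b$equilibrated,
         active_monomials = b$active, law_active = b$law_act,
         representative = pts[1, ], n_points = nrow(pts), points = pts)
  })
  structure(branches[order(names(branches))], class = "tropical_branches")
}

#' @export
print.tropical_branches <- function(x, ...) {
  cat(sprintf("%d branch(es) of tropical equilibrations\n", length(x)))
  for (i in seq_along(x)) {
    b <- x[[i]]
    cat(sprintf("  branch %d (%d points): equilibrated {%s}; rep %s\n",
                i, b$n_points, paste(b$equilibrated, collapse = ", "),
                paste(names(b$representative), b$representative,
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Enumerate branches, including partial equilibrations
#'
#' The complete problem (all two-signed species equilibrated) can be
#' infeasible in parameter regimes where the tropical equations are
#' incompatible, while families of partial equilibrations (a subset of the
#' equations balanced) still organize the dynamics.  This enumerates
#' solutions of the complete problem together with those of each
#' single-species equilibration problem (conservation laws always
#' enforced), then groups the union of all points into branches.
#'
#' @inheritParams build_problem
#' @param domain box half-width used for every run.
#' @param partial also enumerate single-species (partial) equilibration
#'   problems; with `FALSE` only complete equilibrations are grouped.
#' @param solution_cap per-run solution cap.
#' @return a `tropical_branches` object (see [group_branches()]).
#' @export
tropical_branches <- function(system, laws = list(), domain = 6L,
                              partial = TRUE, min_count = 2L,
                              solution_cap = 1e6) {
  complete <- build_problem(system, laws, min_count, domain)
  subsets <- list(complete$target)
  if (partial && length(complete$target) > 1)
    subsets <- c(subsets, as.list(complete$target))
  pts <- NULL
  for (S in subsets) {
    pr <- build_problem(system, laws, min_count, domain, species = S)
    sol <- solve_all(pr, solution_cap)
    if (nrow(sol$orders)) pts <- rbind(pts, sol$orders)
  }
  if (is.null(pts)) return(structure(list(), class = "tropical_branches"))
  group_branches(unique(pts), system, laws)
}

#' Brute-force grid enumeration (reference implementation)
#'
#' Exhaustively tests every integer point of \eqn{[-D, D]^n} against the
#' equilibration condition (positive-side minimum equals negative-side
#' minimum for each required species) and the conservation-law minima.
#' Vectorized over the grid; intended as an independent reference for the
#' constraint solver on small systems, and usable only at desk scale.
#'
#' @inheritParams build_problem
#' @param domain box half-width D.
#' @return matrix of order vectors (one row per solution), ordered as
#'   [solve_all()] orders them.
#' @export
grid_equilibrations <- function(system, laws = list(), domain = 6L,
                                species = NULL, min_count = 2L) {
  order_species <- order_variable_species(system, laws)
  n <- length(order_species)
  grid <- as.matrix(expand.grid(rep(list(seq(-domain, domain)), n)))
  colnames(grid) <- order_species
  ok <- rep(TRUE, nrow(grid))
  signs <- lapply(system$equations, function(eq) vapply(eq, `[[`, 0L, "sign"))
  target <- species %||% order_species[vapply(order_species, function(sp)
    any(signs[[sp]] > 0) && any(signs[[sp]] < 0), TRUE)]
  degs_of <- function(m) m$gamma +
    as.vector(grid[, names(m$exponents), drop = FALSE] %*% m$exponents)
  for (sp in target) {
    eq <- system$equations[[sp]]
    sg <- signs[[sp]]
    D <- vapply(eq, degs_of, numeric(nrow(grid)))
    pos_min <- do.call(pmin, as.data.frame(D[, sg > 0, drop = FALSE]))
    neg_min <- do.call(pmin, as.data.frame(D[, sg < 0, drop = FALSE]))
    ok <- ok & (pos_min == neg_min)
    if (min_count > 2) {
      overall <- pmin(pos_min, neg_min)
      ok <- ok & rowSums(D == overall) >= min_count
    }
  }
  for (l in laws) {
    b <- l$coefficients
    members <- intersect(names(b), order_species)
    if (!length(members)) next
    D <- vapply(members, function(sp)
      parameter_order(b[[sp]], system$epsilon, system$q) + grid[, sp],
      numeric(nrow(grid)))
    ok <- ok & (do.call(pmin, as.data.frame(D)) == l$kappa)
  }
  sols <- grid[ok, , drop = FALSE]
  storage.mode(sols) <- "integer"
  if (nrow(sols) > 1)
    sols <- sols[do.call(order, as.data.frame(sols)), , drop = FALSE]
  rownames(sols) <- NULL
  sols
}
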