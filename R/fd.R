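## Minimal finite-domain constraint kernel: integer variables with interval
## (bounds) domains, affine forms with nonnegative coefficients, and a
## reified minimum-with-count constraint.  Bounds propagation runs to a
## fixpoint; completeness comes from dichotomic search on the variables
## (domain bisection), after which every candidate is verified directly.
##
## This is deliberately small: the only constraint the tropical problem
## needs is "m is a lower bound of a list of affine forms, attained at
## least c_min times", propagated in all directions like a chain of
## reified equalities m #= form_j.

## An affine form: gamma + sum(coef * var[idx]), coef > 0 integers.
fd_form <- function(gamma, idx = integer(), coef = integer()) {
  keep <- coef != 0
  list(gamma = as.numeric(gamma), idx = as.integer(idx[keep]),
       coef = as.numeric(coef[keep]))
}

form_lo <- function(f, lo) f$gamma + sum(f$coef * lo[f$idx])
form_hi <- function(f, hi) f$gamma + sum(f$coef * hi[f$idx])
form_value <- function(f, a) f$gamma + sum(f$coef * a[f$idx])

#' Reified minimum-with-count constraint
#'
#' Declares that `m` is a lower bound of every affine form in `forms` and
#' is attained by at least `c_min` of them (the reified \code{min/3} of the
#' constraint encoding: indicator booleans `B_j <=> m = form_j` summing to
#' the count).  Propagation flows in all directions: fixing `m` prunes the
#' variables of candidate forms, and forms proven strictly above `m`
#' force the remaining candidates down onto it.  On an empty list the count
#' is 0, so the constraint is satisfiable only when `c_min = 0`.
#'
#' Constraints built here are consumed by the internal bounds-propagation
#' solver used by [solve_all()]; [build_problem()] posts one pair of these
#' (sharing `m`) per equilibrated species and one per conservation law.
#'
#' @param forms list of affine forms over the problem's order variables,
#'   each `list(gamma =, idx =, coef =)`.
#' @param m either an integer variable index (`list(var = i)`) or a fixed
#'   integer (`list(const = k)`).
#' @param c_min required number of forms attaining the minimum (default 1).
#' @return a constraint object.
#' @export
min_with_count <- function(forms, m, c_min = 1L) {
  stopifnot(is.list(forms), c_min >= 0)
  structure(list(forms = forms, m = m, c_min = as.integer(c_min)),
            class = "fd_min_count")
}

## One propagation pass of a min-with-count constraint.
## state: list(lo, hi) for all variables (order vars + m vars).
## Returns updated state or NULL on failure.
prop_min_count <- function(cn, state) {
  lo <- state$lo; hi <- state$hi
  nf <- length(cn$forms)
  if (nf == 0) return(if (cn$c_min > 0) NULL else state)
  flo <- vapply(cn$forms, form_lo, 0, lo = lo)
  fhi <- vapply(cn$forms, form_hi, 0, hi = hi)
  if (is.null(cn$m$var)) { mlo <- cn$m$const; mhi <- cn$m$const }
  else { mlo <- lo[cn$m$var]; mhi <- hi[cn$m$var] }

  ## m <= every form  =>  m.hi <= min f.hi ; attained => m.lo >= min f.lo
  mhi <- min(mhi, min(fhi))
  if (cn$c_min >= 1) mlo <- max(mlo, min(flo))
  if (mlo > mhi) return(NULL)

  ## every form >= m.lo: tighten variable lower bounds
  for (j in seq_len(nf)) {
    f <- cn$forms[[j]]
    if (flo[j] >= mlo || !length(f$idx)) {
      if (flo[j] < mlo && !length(f$idx)) return(NULL)
      next
    }
    for (t in seq_along(f$idx)) {
      i <- f$idx[t]; c_i <- f$coef[t]
      rest_hi <- fhi[j] - c_i * hi[i]
      lb <- ceiling((mlo - rest_hi) / c_i - 1e-9)
      if (lb > lo[i]) { lo[i] <- lb; if (lo[i] > hi[i]) return(NULL) }
    }
    flo[j] <- form_lo(f, lo)
  }

  ## candidate forms able to attain m; exactly c_min candidates => forced
  cand <- which(flo <= mhi + 1e-9)
  if (length(cand) < cn$c_min) return(NULL)
  if (cn$c_min >= 1 && length(cand) == cn$c_min) {
    mlo <- max(mlo, max(flo[cand]))
    if (mlo > mhi) return(NULL)
    for (j in cand) {
      f <- cn$forms[[j]]
      for (t in seq_along(f$idx)) {
        i <- f$idx[t]; c_i <- f$coef[t]
        rest_lo <- flo[j] - c_i * lo[i]
        ub <- floor((mhi - rest_lo) / c_i + 1e-9)
        if (ub < hi[i]) { hi[i] <- ub; if (lo[i] > hi[i]) return(NULL) }
      }
      flo[j] <- form_lo(f, lo)
    }
  }
  if (!is.null(cn$m$var)) {
    lo[cn$m$var] <- mlo; hi[cn$m$var] <- mhi
  } else if (mlo > cn$m$const || mhi < cn$m$const) return(NULL)
  list(lo = lo, hi = hi)
}

## Propagate all constraints to a fixpoint; NULL on failure.
fd_propagate <- function(constraints, state, max_iter = 1000L) {
  for (iter in seq_len(max_iter)) {
    before <- c(state$lo, state$hi)
    for (cn in constraints) {
      state <- prop_min_count(cn, state)
      if (is.null(state)) return(NULL)
    }
    if (identical(c(state$lo, state$hi), before)) return(state)
  }
  state
}

## Direct (non-propagated) check that a full assignment satisfies a
## constraint: m equals the minimum-side bound and is attained c_min times.
check_min_count <- function(cn, a) {
  if (!length(cn$forms)) return(cn$c_min == 0)
  vals <- vapply(cn$forms, form_value, 0, a = a)
  m <- if (is.null(cn$m$var)) cn$m$const else a[cn$m$var]
  all(vals >= m) && sum(vals == m) >= cn$c_min
}

## Complete enumeration by bisection over branch_vars.  free_vars (in no
## constraint) are expanded as a cross product at each leaf.  Calls
## `emit(assignment)` for each solution; emit returns FALSE to stop (cap).
fd_enumerate <- function(constraints, state, branch_vars, free_vars, emit) {
  recurse <- function(state) {
    state <- fd_propagate(constraints, state)
    if (is.null(state)) return(TRUE)
    unfixed <- branch_vars[state$lo[branch_vars] < state$hi[branch_vars]]
    if (!length(unfixed)) {
      a <- state$lo
      if (!all(vapply(constraints, check_min_count, TRUE, a = a))) return(TRUE)
      if (!length(free_vars)) return(emit(a))
      grids <- lapply(free_vars, function(i) state$lo[i]:state$hi[i])
      g <- as.matrix(expand.grid(grids))
      for (r in seq_len(nrow(g))) {
        a[free_vars] <- g[r, ]
        if (!emit(a)) return(FALSE)
      }
      return(TRUE)
    }
    v <- unfixed[[1]]
    mid <- floor((state$lo[v] + state$hi[v]) / 2)
    left <- state; left$hi[v] <- mid
    if (!recurse(left)) return(FALSE)
    right <- state; right$lo[v] <- mid + 1
    recurse(right)
  }
  recurse(state)
}
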