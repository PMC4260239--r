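#' Tropical equilibration analysis of a reaction network
#'
#' One-stop analysis: parses the model (SBML or plain-text reaction format)
#' if given as a path, builds the signed-monomial ODE system, computes (or
#' accepts) conservation laws with their constant orders, solves the
#' equilibration constraint problem with iterative domain expansion,
#' groups the solutions into branches, and optionally derives the
#' tropically truncated system at each branch representative.
#'
#' @param x a file path, a [reaction_network()], or a [polynomial_system()].
#' @param epsilon small parameter in (0, 1); default 0.1.
#' @param laws `NULL` to compute conservation laws from the stoichiometric
#'   matrix, a list of laws/coefficient vectors, or a path to a side-car
#'   JSON/TSV file (see [read_laws()]).
#' @param min_count required multiplicity of each equation's minimum.
#' @param domain initial domain half-width of the expansion schedule.
#' @param max_domain final half-width (default 128).
#' @param solution_cap enumeration cap.
#' @param partial_branches include partial equilibrations when grouping
#'   branches (see [tropical_branches()]).
#' @param reduce derive truncated systems at branch representatives.
#' @param q order denominator pre-multiplier, see [parameter_order()].
#' @return an object of class `tropical_analysis` with components
#'   `network`, `system`, `laws`, `solutions` (a `tropical_solutions`),
#'   `branches`, `reductions` and `config`.
#' @examples
#' fit <- tropicalize(michaelis_menten_full(0, 0, 1, 1), epsilon = 0.1)
#' fit
#' summary(fit)
#' @export
tropicalize <- function(x, epsilon = 0.1, laws = NULL, min_count = 2L,
                        domain = 2L, max_domain = 128L, solution_cap = 1e6,
                        partial_branches = TRUE, reduce = FALSE, q = 1L) {
  network <- NULL
  if (is.character(x)) x <- read_model(x)
  if (inherits(x, "reaction_network")) {
    network <- x
    system <- build_odes(network, epsilon, q)
  } else if (inherits(x, "polynomial_system")) {
    system <- x
    network <- system$network
  } else stop("cannot analyse an object of class ", class(x)[1])

  if (is.character(laws)) laws <- read_laws(laws, epsilon, q)
  if (is.null(laws)) {
    laws <- find_invariants(system)
    laws <- if (!is.null(network)) attach_constants(laws, network, epsilon, q)
    else list()   # no initial concentrations: no constant orders available
  } else {
    plain <- !vapply(laws, inherits, TRUE, "conservation_law")
    if (any(plain)) {
      if (is.null(network))
        stop("laws without constants need a network with initial concentrations")
      laws <- c(laws[!plain], attach_constants(laws[plain], network, epsilon, q))
    }
  }

  problem <- build_problem(system, laws, min_count, domain)
  solutions <- solve_with_expansion(problem, solution_cap, max_domain)
  branches <- tropical_branches(system, laws, domain = solutions$domain_used,
                                partial = partial_branches,
                                min_count = min_count,
                                solution_cap = solution_cap)
  reductions <- if (reduce) lapply(branches, function(b) {
    tr <- truncate_system(system, b$representative)
    list(truncation = tr, pools = find_new_pools(tr))
  })
  structure(list(network = network, system = system, laws = laws,
                 problem = problem, solutions = solutions,
                 branches = branches, reductions = reductions,
                 config = list(epsilon = epsilon, min_count = min_count,
                               domain = domain, max_domain = max_domain,
                               solution_cap = solution_cap, q = q)),
            class = "tropical_analysis")
}

read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) read_sbml(path)
  else read_reaction_text(path)
}

#' @export
print.tropical_analysis <- function(x, ...) {
  ns <- nrow(x$solutions$orders)
  cat("Tropical equilibration analysis\n")
  cat(sprintf("  %d species, %d conservation law(s), epsilon = %g\n",
              length(x$system$species), length(x$laws), x$system$epsilon))
  cat(sprintf("  complete equilibrations: %d (domain [-%d, %d])\n",
              ns, x$solutions$domain_used, x$solutions$domain_used))
  cat(sprintf("  branches: %d\n", length(x$branches)))
  if (length(x$solutions$excluded_variables))
    cat("  excluded variables:",
        paste(x$solutions$excluded_variables, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tropical_analysis <- function(object, ...) {
  print(object)
  cat("\nSystem:\n"); print(object$system)
  if (length(object$laws)) {
    cat("Conservation laws:\n")
    for (l in object$laws) { cat("  "); print(l) }
  }
  print(object$branches)
  if (!is.null(object$reductions)) {
    cat("\nTruncated systems at branch representatives:\n")
    for (r in object$reductions) print(r$truncation)
  }
  invisible(object)
}

#' Plot equilibration branches in the order plane
#'
#' For systems with exactly two order variables, plots the solution points
#' in the \eqn{(a_1, a_2)} plane coloured by branch, the discrete analogue
#' of the tropical-curve picture.
#'
#' @param x a `tropical_analysis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tropical_analysis <- function(x, ...) {
  br <- x$branches
  if (!length(br)) { warning("no branches to plot"); return(invisible(x)) }
  pts <- do.call(rbind, lapply(seq_along(br), function(i)
    cbind(br[[i]]$points, branch = i)))
  if (ncol(pts) != 3)
    stop("branch plot requires exactly two order variables")
  graphics::plot(pts[, 1], pts[, 2], col = pts[, 3], pch = 19,
                 xlab = colnames(pts)[1], ylab = colnames(pts)[2], ...)
  graphics::legend("topleft", legend = paste("branch", seq_along(br)),
                   col = seq_along(br), pch = 19, bty = "n")
  invisible(x)
}

## ---- machine-readable reports ----

solutions_jsonl <- function(solutions, file = stdout()) {
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  for (s in solutions$solutions) {
    rec <- list(orders = as.list(s$orders),
                achieved_min = as.list(
                  s$achieved_minimum[!is.na(s$achieved_minimum)]),
                equilibrated = I(s$equilibrated),
                active = s$active_monomials)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(solutions)
}

#' Analyse one model file and produce a report
#'
#' Runs the full pipeline on a model file and returns a schema-stable,
#' JSON-able report: polynomial-kinetics status, model sizes, the
#' conservation laws used, a solution-set summary (count, domain used,
#' boundary/truncation flags, excluded variables) and equilibration status
#' (`"complete"`, `"partial"`, or `"none"`).  A model whose kinetics are
#' rejected as non-polynomial is reported as such, with no solving
#' attempted; this mirrors how repository-scale screens filter models.
#'
#' @param path model file (SBML `.xml`/`.sbml` or plain-text reactions).
#' @param epsilon,laws,min_count,domain,max_domain,solution_cap,q see
#'   [tropicalize()].
#' @param reduce include truncated systems per branch in the report.
#' @return a list (report); `report$status` is `"ok"`, `"nonpolynomial"`
#'   or `"error"`.
#' @export
run_model <- function(path, epsilon = 0.1, laws = NULL, min_count = 2L,
                      domain = 2L, max_domain = 128L, solution_cap = 1e6,
                      reduce = FALSE, q = 1L) {
  t0 <- proc.time()[["elapsed"]]
  report <- list(model = basename(path), status = "ok")
  fit <- tryCatch(
    tropicalize(path, epsilon = epsilon, laws = laws, min_count = min_count,
                domain = domain, max_domain = max_domain,
                solution_cap = solution_cap, reduce = reduce, q = q),
    tropicaleq_nonpolynomial = function(e) {
      report$status <<- "nonpolynomial"
      report$reason <<- conditionMessage(e)
      NULL
    },
    tropicaleq_nothing_to_equilibrate = function(e) {
      report$status <<- "nothing_to_equilibrate"
      NULL
    },
    error = function(e) {
      report$status <<- "error"
      report$reason <<- conditionMessage(e)
      NULL
    })
  if (!is.null(fit)) {
    sol <- fit$solutions
    n_complete <- nrow(sol$orders)
    any_partial <- length(fit$branches) > 0
    report <- c(report, list(
      n_species = length(fit$system$species),
      n_reactions = if (!is.null(fit$network)) n_reactions(fit$network),
      n_laws = length(fit$laws),
      laws = lapply(fit$laws, function(l)
        list(coefficients = as.list(l$coefficients), constant = l$constant,
             kappa = l$kappa)),
      n_solutions = n_complete,
      n_branches = length(fit$branches),
      domain_used = sol$domain_used,
      boundary_hit = sol$boundary_hit,
      truncated_enumeration = sol$truncated,
      excluded_variables = I(sol$excluded_variables),
      equilibration = if (n_complete > 0) "complete"
                      else if (any_partial) "partial" else "none"))
    if (reduce)
      report$reductions <- lapply(fit$reductions, function(r)
        truncation_record(r$truncation, r$pools))
  }
  report$time_s <- round(proc.time()[["elapsed"]] - t0, 3)
  report
}

#' Batch analysis of a directory of model files
#'
#' Applies [run_model()] to every model file in a directory (lexicographic
#' filename order), collecting per-model rows and aggregate counts of
#' complete / partial / no equilibration, in the shape of a
#' repository-screen summary table.  Per-model failures are recorded as
#' error rows and the batch continues.
#'
#' @param dir directory containing `.xml`, `.sbml` or `.txt` model files.
#' @param ... passed to [run_model()].
#' @return data frame (one row per model) with an `aggregate` attribute.
#' @export
batch_models <- function(dir, ...) {
  files <- sort(list.files(dir, pattern = "\\.(xml|sbml|txt)$",
                           full.names = TRUE, ignore.case = TRUE))
  rows <- lapply(files, function(f) {
    r <- tryCatch(run_model(f, ...),
                  error = function(e) list(model = basename(f),
                                           status = "error",
                                           reason = conditionMessage(e)))
    data.frame(model = r$model, status = r$status,
               equilibration = r$equilibration %||% NA_character_,
               n_species = r$n_species %||% NA_integer_,
               n_solutions = r$n_solutions %||% NA_integer_,
               n_branches = r$n_branches %||% NA_integer_,
               domain_used = r$domain_used %||% NA_integer_,
               time_s = r$time_s %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(model = character(), status = character(),
                  equilibration = character(), n_species = integer(),
                  n_solutions = integer(), n_branches = integer(),
                  domain_used = integer(), time_s = numeric(),
                  stringsAsFactors = FALSE)
  attr(tab, "aggregate") <- list(
    n_models = nrow(tab),
    complete = sum(tab$equilibration %in% "complete"),
    partial = sum(tab$equilibration %in% "partial"),
    none = sum(tab$equilibration %in% "none"),
    nonpolynomial = sum(tab$status == "nonpolynomial"),
    errors = sum(tab$status == "error"))
  tab
}
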