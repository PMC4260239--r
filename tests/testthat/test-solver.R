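test_that("reduced Michaelis-Menten solutions lie on the two known half-lines", {
  ## gamma1 = 0, gamma_rev = 0, gamma2 = 1, gamma_e = 1: solutions sit on
  ## a2 = gamma_e (a1 < 0) or a2 = a1 + gamma1 + gamma_e - gamma_rev (a1 > 0)
  sys <- do.call(michaelis_menten_reduced, as.list(mm_regime_slow_product))
  sol <- solve_all(build_problem(sys, domain = 4))
  expect_identical(unname(sol$orders), unname(oracle_solutions(sys, D = 4)))
  a1 <- sol$orders[, "x1"]; a2 <- sol$orders[, "x2"]
  expect_true(all((a2 == 1 & a1 <= 0) | (a2 == a1 + 1 & a1 >= 0)))
  expect_true(sol$boundary_hit)   # half-lines reach the box edge
  expect_false(sol$truncated)
})

test_that("the conservation-law constraint enters as a minimum over member orders", {
  mm <- michaelis_menten_conserved(0, 0, 1, 1)
  pr <- build_problem(mm$system, mm$laws, domain = 4)
  law_cns <- Filter(function(cn) !is.null(cn$m$const), pr$constraints)
  expect_length(law_cns, 1)
  expect_equal(law_cns[[1]]$m$const, 1)            # kappa = gamma_e
  expect_length(law_cns[[1]]$forms, 2)             # min(a2, a3)
  ## and the solved set agrees with brute force under that constraint
  sol <- solve_all(pr)
  expect_identical(unname(sol$orders),
                   unname(oracle_solutions(mm$system, mm$laws, D = 4)))
})

test_that("single-signed and inert species are excluded, empty problems are distinguishable", {
  sys <- build_odes(parse_reaction_text("-> X ; k=1"))
  expect_error(build_problem(sys), class = "tropicaleq_nothing_to_equilibrate")
  ## a production-only species rides along an otherwise solvable problem
  sys2 <- build_odes(parse_reaction_text(c("-> X ; k=1", "X -> Y ; k=1")))
  pr <- build_problem(sys2)
  expect_named(pr$excluded, "Y")
  sol <- solve_all(pr)
  expect_true("Y" %in% sol$excluded_variables)
})

test_that("degenerate single-equation problems solve exactly", {
  sys <- build_odes(parse_reaction_text(c("-> X ; k=1", "X -> ; k=1")))
  sol <- solve_all(build_problem(sys, domain = 2))
  expect_equal(unname(sol$orders), matrix(0L, 1, 1))
  ## unsatisfiable conservation constraint empties the solution set
  law <- conservation_law(c(X = 1L), 1e-3, 0.1)   # kappa = 3 > domain
  sol2 <- solve_all(build_problem(sys, list(law), domain = 2))
  expect_equal(nrow(sol2$orders), 0)
})

test_that("domain expansion doubles until the first feasible box", {
  sys <- build_odes(parse_reaction_text(c("-> X ; k=1", "X -> ; k=1e-5")))
  pr <- build_problem(sys, domain = 2)
  expect_equal(nrow(solve_all(pr, domain = 2)$orders), 0)
  expect_equal(nrow(solve_all(pr, domain = 4)$orders), 0)
  sol <- solve_with_expansion(pr)
  expect_equal(sol$domain_used, 8)
  expect_equal(unname(sol$orders), matrix(-5L, 1, 1))

  ## solvable at the initial domain: no expansion happens
  sys0 <- build_odes(parse_reaction_text(c("-> X ; k=1", "X -> ; k=1")))
  sol0 <- solve_with_expansion(build_problem(sys0, domain = 2))
  expect_equal(sol0$domain_used, 2)

  ## infeasible at every domain: empty set at the expansion limit
  law <- conservation_law(c(X = 1L), 1e-3, 0.1)
  bad <- build_problem(sys0, list(law), domain = 2)
  solbad <- solve_with_expansion(bad, max_domain = 16L)
  expect_equal(nrow(solbad$orders), 0)
  expect_equal(solbad$domain_used, 16)
})

test_that("solution sets are monotone in the domain half-width", {
  n_checked <- 0L
  for (seed in 1:8) {
    net <- random_network(3, 4, seed = seed)
    sys <- build_odes(net)
    if (!length(equilibratable_species(sys))) next
    pr <- build_problem(sys)
    small <- solve_all(pr, domain = 3)$orders
    big <- solve_all(pr, domain = 6)$orders
    keys <- function(m) apply(m, 1, paste, collapse = ",")
    expect_true(all(keys(small) %in% keys(big)))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 2)
})

test_that("solver equals the brute-force grid oracle on seeded random networks", {
  for (seed in 1:10) {
    net <- random_network(2 + seed %% 3, 2 + seed %% 5, seed = 100 + seed)
    sys <- build_odes(net)
    laws <- attach_constants(find_invariants(net), net, 0.1)
    if (!length(equilibratable_species(sys))) {
      expect_error(build_problem(sys, laws),
                   class = "tropicaleq_nothing_to_equilibrate")
      next
    }
    sol <- solve_all(build_problem(sys, laws), domain = 4)
    expect_identical(unname(sol$orders),
                     unname(oracle_solutions(sys, laws, D = 4)),
                     info = paste("seed", 100 + seed))
    ## the vectorized package reference agrees too
    expect_identical(unname(sol$orders),
                     unname(grid_equilibrations(sys, laws, domain = 4)))
  }
})

test_that("every reported solution is sound under direct classification", {
  mm <- michaelis_menten_conserved(0, 2, 0, 1)
  pr <- build_problem(mm$system, mm$laws, species = "x1", domain = 5)
  sol <- solve_all(pr)
  expect_gt(nrow(sol$orders), 0)
  for (s in sol$solutions) {
    expect_true("x1" %in% s$equilibrated)
    for (l in mm$laws) {
      degs <- s$orders[names(l$coefficients)]
      expect_equal(min(degs), l$kappa)
    }
  }
})

test_that("classification separates complete and partial equilibration points", {
  sysB <- do.call(michaelis_menten_reduced, as.list(mm_regime_fast_product))
  both <- classify_solution(sysB, c(x1 = -1L, x2 = 1L))
  expect_setequal(both$equilibrated, c("x1", "x2"))
  only2 <- classify_solution(sysB, c(x1 = 1L, x2 = 2L))
  expect_identical(only2$equilibrated, "x2")
  only1 <- classify_solution(sysB, c(x1 = 3L, x2 = 2L))
  expect_identical(only1$equilibrated, "x1")
  ## a point where the positive minimum undercuts the negative one
  off <- classify_solution(sysB, c(x1 = -3L, x2 = 3L))
  expect_false("x1" %in% off$equilibrated)
})

test_that("shifting one equation's coefficient orders shifts its minimum, not the solutions", {
  sys <- do.call(michaelis_menten_reduced, as.list(mm_regime_slow_product))
  shifted <- sys
  delta <- 3L
  shifted$equations$x1 <- lapply(shifted$equations$x1, function(m) {
    m$gamma <- m$gamma + delta
    m$components <- lapply(m$components, function(cp) {
      cp$gamma <- cp$gamma + delta; cp })
    m
  })
  a <- solve_all(build_problem(sys, domain = 4))
  b <- solve_all(build_problem(shifted, domain = 4))
  expect_identical(a$orders, b$orders)
  for (i in seq_len(nrow(a$orders))) {
    ca <- classify_solution(sys, a$orders[i, ])
    cb <- classify_solution(shifted, b$orders[i, ])
    expect_identical(cb$achieved_minimum[["x1"]],
                     ca$achieved_minimum[["x1"]] + delta)
  }
})

test_that("branch grouping returns one class per dominance structure", {
  sysA <- do.call(michaelis_menten_reduced, as.list(mm_regime_slow_product))
  brA <- tropical_branches(sysA, domain = 6)
  expect_length(brA, 2)
  ## a singleton solution set forms a single branch
  one <- group_branches(matrix(c(x1 = 0L, x2 = 1L), 1,
                               dimnames = list(NULL, c("x1", "x2"))),
                        sysA)
  expect_length(one, 1)
  expect_equal(one[[1]]$n_points, 1)
})
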