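test_that("full Michaelis-Menten yields exactly the two semi-positive invariants", {
  net <- michaelis_menten_full(0, 0, 1, 1)
  laws <- find_invariants(net)
  vecs <- lapply(laws, function(b) b[net$species])
  expect_length(vecs, 2)
  expect_true(any(vapply(vecs, function(b)
    identical(unname(b), c(0L, 1L, 1L, 0L)), TRUE)))   # ES + E conserved
  expect_true(any(vapply(vecs, function(b)
    identical(unname(b), c(1L, 1L, 0L, 1L)), TRUE)))   # S + ES + P conserved
  S <- stoichiometric_matrix(net)
  for (b in laws) expect_true(all(b[rownames(S)] %*% S == 0))
})

test_that("the reduced two-variable system has no semi-positive invariant", {
  expect_length(find_invariants(michaelis_menten_reduced(0, 0, 1, 1)), 0)
  ## same conclusion from the monomial coefficient matrix route
  sys <- michaelis_menten_reduced(0, 0, 1, 1)
  sys$stoichiometric_matrix <- NULL
  expect_length(find_invariants(sys), 0)
})

test_that("invariants generate the same cone as exhaustive bounded enumeration", {
  in_cone <- function(b, gens) {
    ## b expressible as a nonnegative combination of the generators
    if (!length(gens)) return(all(b == 0))
    G <- do.call(cbind, gens)
    fit <- pracma::lsqnonneg(G, as.numeric(b))
    sqrt(sum((G %*% fit$x - b)^2)) < 1e-8
  }
  for (seed in 1:8) {
    net <- random_network(3 + seed %% 3, 2 + seed %% 5, seed = seed)
    S <- stoichiometric_matrix(net)
    got <- lapply(find_invariants(net), function(b) b[rownames(S)])
    want <- oracle_invariants(S, bound = 3)
    ## every found vector is a semi-positive left-kernel vector with gcd 1
    for (b in got) {
      expect_true(all(b %*% S == 0))
      expect_true(all(b >= 0) && any(b > 0))
      expect_equal(tropicaleq:::gcd_vec(b[b > 0]), 1)
    }
    ## supports are pairwise minimal
    for (b in got) for (b2 in got)
      if (!identical(b, b2))
        expect_false(all(which(b2 > 0) %in% which(b > 0)) &&
                       length(which(b2 > 0)) < length(which(b > 0)))
    ## every bounded brute-force kernel vector lies in the generated cone
    ## (the generators themselves may need entries beyond the brute bound,
    ## so only this direction is decidable from the bounded enumeration)
    for (b in want)
      expect_true(in_cone(b, got), info = paste("seed", seed, "missing",
                                                paste(b, collapse = ",")))
  }
})

test_that("a reaction strictly producing a law member destroys that law", {
  base <- michaelis_menten_full(0, 0, 1, 1)
  plus <- reaction_network(
    base$species,
    c(base$reactions, list(reaction(NULL, c(x3 = 1), 1, id = "source"))),
    base$init)
  laws <- find_invariants(plus)
  vecs <- lapply(laws, function(b) unname(b[base$species]))
  expect_false(any(vapply(vecs, identical, TRUE, c(0L, 1L, 1L, 0L))))
  expect_true(any(vapply(vecs, identical, TRUE, c(1L, 1L, 0L, 1L))))
})

test_that("attach_constants computes kappa from the initial linear form", {
  net <- michaelis_menten_full(0, 0, 1, 2)   # gamma_e = 2: e0 = 0.01
  laws <- attach_constants(find_invariants(net), net, 0.1)
  by_members <- stats::setNames(laws, vapply(laws, function(l)
    paste(sort(names(l$coefficients)), collapse = "+"), ""))
  expect_equal(by_members[["x2+x3"]]$constant, 0.01)
  expect_identical(by_members[["x2+x3"]]$kappa, 2L)
  expect_equal(by_members[["x1+x2+x4"]]$constant, 1)
  expect_identical(by_members[["x1+x2+x4"]]$kappa, 0L)

  ## zero initial total: dropped with a warning
  empty_net <- reaction_network(net$species, net$reactions,
                                init = c(x1 = 1))   # no enzyme at all
  expect_warning(kept <- attach_constants(find_invariants(net), empty_net, 0.1),
                 "zero initial total")
  expect_length(kept, 1)
})

test_that("side-car law files (JSON and TSV) round-trip coefficients and constants", {
  json <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(coefficients = list(x2 = 1, x3 = 1), constant = 0.01),
    list(coefficients = list(x1 = 1, x2 = 1, x4 = 1))),
    auto_unbox = TRUE), json)
  laws <- read_laws(json, epsilon = 0.1)
  expect_s3_class(laws[[1]], "conservation_law")
  expect_identical(laws[[1]]$kappa, 2L)
  expect_type(laws[[2]], "integer")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("law\tspecies\tcoefficient\tconstant",
               "L1\tx2\t1\t0.1", "L1\tx3\t1\t0.1"), tsv)
  tl <- read_laws(tsv, epsilon = 0.1)
  expect_length(tl, 1)
  expect_identical(tl[[1]]$kappa, 1L)
  expect_equal(tl[[1]]$coefficients, c(x2 = 1L, x3 = 1L))
})
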