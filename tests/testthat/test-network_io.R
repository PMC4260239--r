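test_that("plain-text reactions parse with stoichiometry, accumulation and init block", {
  net <- parse_reaction_text(c(
    "# three-reaction enzymatic mechanism",
    "init: x1=1",
    "init: x3=0.01",
    "x1 + x3 -> x2 ; k=1.0",
    "x2 -> x1 + x3 ; k=0.5",
    "x2 -> x3 + x4 ; k=0.1"))
  expect_s3_class(net, "reaction_network")
  expect_length(net$species, 4)
  expect_length(net$reactions, 3)
  expect_equal(net$init[["x3"]], 0.01)
  expect_equal(net$reactions[[1]]$reactants, c(x1 = 1L, x3 = 1L))

  bi <- parse_reaction_text("2 A -> B ; k=0.5")
  expect_equal(bi$reactions[[1]]$reactants, c(A = 2L))

  dup <- parse_reaction_text("A + A -> B ; k=1")
  expect_equal(dup$reactions[[1]]$reactants, c(A = 2L))

  empty <- parse_reaction_text("")
  expect_length(empty$species, 0)
  expect_length(empty$reactions, 0)

  prod_only <- parse_reaction_text("-> A ; k=2")
  expect_equal(prod_only$reactions[[1]]$products, c(A = 1L))
  expect_length(prod_only$reactions[[1]]$reactants, 0)
})

test_that("text parser reports syntax errors with line numbers and rejects k <= 0", {
  expect_error(parse_reaction_text(c("A -> B ; k=1", "A -> B")), "line 2")
  expect_error(parse_reaction_text("A -> B ; k=0"), "nonpositive")
  expect_error(parse_reaction_text("A -> B ; k=-1"), "nonpositive")
  expect_error(parse_reaction_text("A & B -> C ; k=1"), "syntax")
})

test_that("render/parse round-trips species, stoichiometries and rate constants", {
  for (seed in 1:5) {
    net <- random_network(4, 5, seed = seed)
    back <- parse_reaction_text(render_reaction_text(net))
    expect_setequal(back$species, net$species)
    expect_equal(back$init[net$species], net$init)
    expect_equal(lapply(back$reactions, function(r) r$reactants[order(names(r$reactants))]),
                 lapply(net$reactions, function(r) r$reactants[order(names(r$reactants))]))
    expect_equal(vapply(back$reactions, `[[`, 0, "k"),
                 vapply(net$reactions, `[[`, 0, "k"))
  }
})

test_that("SBML mass-action model resolves local and global parameters", {
  path <- system.file("extdata", "mm_mass_action.xml", package = "tropicaleq")
  net <- read_sbml(path)
  expect_length(net$species, 4)
  expect_length(net$reactions, 3)
  ks <- stats::setNames(vapply(net$reactions, `[[`, 0, "k"),
                        vapply(net$reactions, `[[`, "", "id"))
  expect_equal(ks[["bind"]], 1)
  expect_equal(ks[["cat"]], 0.1)   # local parameter shadowing scope
  expect_equal(net$init[["E"]], 0.1)
  ## every kinetic law is a single mass-action monomial: never rejected
  expect_s3_class(net, "reaction_network")
})

test_that("SBML with expanded polynomial law splits terms and folds boundary species", {
  path <- system.file("extdata", "mm_expanded_l3.xml", package = "tropicaleq")
  net <- read_sbml(path)
  expect_setequal(net$species, c("S", "ES"))   # Etot is a boundary constant
  sys <- build_odes(net)
  labs <- lapply(sys$equations, function(eq)
    sort(vapply(eq, tropicaleq:::monomial_label, "")))
  expect_equal(labs$S, c("+ES", "+ES*S", "-S"))
  expect_equal(labs$ES, c("+S", "-ES", "-ES*S"))
  mag <- function(sp, lab) {
    eq <- sys$equations[[sp]]
    eq[[which(vapply(eq, tropicaleq:::monomial_label, "") == lab)]]$magnitude
  }
  expect_equal(mag("S", "-S"), 0.1)      # k1 * Etot
  expect_equal(mag("S", "+ES"), 0.01)    # e-notation constant
})

test_that("rational kinetics raise a distinguishable rejection carrying the reaction id", {
  path <- system.file("extdata", "mm_rational.xml", package = "tropicaleq")
  err <- tryCatch(read_sbml(path), tropicaleq_nonpolynomial = function(e) e)
  expect_s3_class(err, "tropicaleq_nonpolynomial")
  expect_equal(err$reaction, "conv")
})

test_that("SBML edge cases: empty reaction list, missing file, malformed document", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="empty"><listOfSpecies>',
    '<species id="A" compartment="c" initialConcentration="1"/>',
    '</listOfSpecies></model></sbml>'), tmp)
  net <- read_sbml(tmp)
  expect_equal(net$species, "A")
  expect_length(net$reactions, 0)

  expect_error(read_sbml(file.path(tempdir(), "no_such_model.xml")), "not found")

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", bad)
  expect_error(read_sbml(bad))
})
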