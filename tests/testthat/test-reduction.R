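test_that("truncation keeps exactly the minimal-degree monomials", {
  sys <- do.call(michaelis_menten_reduced, as.list(mm_regime_slow_product))
  tr <- truncate_system(sys, c(x1 = 1L, x2 = 2L))
  for (sp in sys$species) {
    degs_kept <- vapply(tr$retained[[sp]], monomial_degree, 0L, a = tr$orders)
    degs_drop <- vapply(tr$dropped[[sp]], monomial_degree, 0L, a = tr$orders)
    mn <- min(c(degs_kept, degs_drop))
    expect_true(all(degs_kept == mn))
    if (length(degs_drop)) expect_true(all(degs_drop > mn))
    expect_identical(tr$timescale_exponents[[sp]],
                     as.integer(mn - tr$orders[[sp]]))
  }
})

test_that("a system whose every monomial is active truncates to itself and is idempotent", {
  sys <- build_odes(parse_reaction_text(c("-> X ; k=1", "X -> ; k=1")))
  tr <- truncate_system(sys, c(X = 0L))
  expect_equal(lapply(tr$retained, length), lapply(sys$equations, length))
  expect_length(tr$dropped$X, 0)
  tr2 <- truncate_system(tr, c(X = 0L))
  expect_equal(retained_labels(tr2), retained_labels(tr))

  sysA <- do.call(michaelis_menten_reduced, as.list(mm_regime_slow_product))
  trA <- truncate_system(sysA, c(x1 = 1L, x2 = 2L))
  trA2 <- truncate_system(trA, c(x1 = 1L, x2 = 2L))
  expect_equal(retained_labels(trA2), retained_labels(trA))
})

test_that("quasi-equilibrium truncation splits the dominated part of a merged coefficient", {
  ## regime where the product step is slower: truncation at the branch
  ## a2 = a1 + gamma1 + gamma_e - gamma_rev keeps -k1 e0 x1 + k-1 x2 and
  ## its mirror; the k2 part of the merged (k-1 + k2) x2 coefficient is
  ## dominated and must move to the dropped terms
  sys <- do.call(michaelis_menten_reduced, as.list(mm_regime_slow_product))
  tr <- truncate_system(sys, c(x1 = 1L, x2 = 2L))
  expect_equal(retained_labels(tr), list(x1 = c("+x2", "-x1"),
                                         x2 = c("+x1", "-x2")))
  x2_neg <- Filter(function(m) m$sign < 0, tr$retained$x2)[[1]]
  expect_equal(x2_neg$magnitude, 1)        # k-1 only, k2 = 0.1 dropped
  drop_labels <- sort(vapply(tr$dropped$x2, tropicaleq:::monomial_label, ""))
  expect_equal(drop_labels, c("-x1*x2", "-x2"))
})

test_that("timescale ordering identifies fast and slow variables per regime", {
  ## low enzyme (gamma1 + gamma_e > gamma2): complex is the fast variable
  sys_low <- michaelis_menten_reduced(0, 3, 1, 2)   # rev slow, e0 = eps^2
  tr_low <- truncate_system(sys_low, c(x1 = 2L, x2 = 3L))
  ord_low <- order_timescales(tr_low)
  expect_equal(ord_low$species, c("x2", "x1"))
  expect_equal(ord_low$exponent, c(1L, 2L))   # gamma2, gamma1 + gamma_e

  ## high enzyme (gamma1 + gamma_e < gamma2): substrate is faster
  sys_high <- michaelis_menten_reduced(0, 2, 1, 0)
  tr_high <- truncate_system(sys_high, c(x1 = 3L, x2 = 1L))
  ord_high <- order_timescales(tr_high)
  expect_equal(ord_high$species, c("x1", "x2"))
  expect_equal(ord_high$exponent, c(0L, 1L))

  ## an inert system yields an empty ordering
  inert <- build_odes(parse_reaction_text(c("A -> 2 A ; k=1", "A -> ; k=1")))
  expect_equal(nrow(order_timescales(truncate_system(inert, c(A = 0L)))), 0)
})

test_that("pool detection finds truncation-only conserved sums with their drivers", {
  sys <- do.call(michaelis_menten_reduced, as.list(mm_regime_slow_product))
  ## quasi-equilibrium branch: z = x1 + x2 conserved by the fast dynamics
  tr <- truncate_system(sys, c(x1 = 1L, x2 = 2L))
  pools <- find_new_pools(tr)
  expect_length(pools, 1)
  expect_equal(pools[[1]]$coefficients, c(x1 = 1L, x2 = 1L))
  expect_equal(vapply(pools[[1]]$driving, tropicaleq:::monomial_label, ""), "-x2")
  expect_equal(pools[[1]]$driving[[1]]$magnitude, 0.1)   # the rate of the slow step

  ## each pool annihilates the truncated coefficients but not the full ones
  Ct <- tropicaleq:::monomial_matrix(sys, tr$retained)
  Cf <- tropicaleq:::monomial_matrix(sys)
  b <- pools[[1]]$coefficients
  expect_true(all(abs(b %*% Ct[names(b), ]) < 1e-12))
  expect_gt(max(abs(b %*% Cf[names(b), ])), 0)

  ## quasi-stationarity branch: kernel adds nothing beyond the full system
  sysB <- do.call(michaelis_menten_reduced, as.list(mm_regime_fast_product))
  trB <- truncate_system(sysB, c(x1 = 1L, x2 = 2L))
  expect_length(find_new_pools(trB), 0)

  ## truncation equal to the full system reports no pool either
  ident <- build_odes(parse_reaction_text(c("-> X ; k=1", "X -> ; k=1")))
  expect_length(find_new_pools(truncate_system(ident, c(X = 0L))), 0)
})
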