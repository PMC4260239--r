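# tropicaleq

Tropical equilibration and model reduction for mass-action reaction
networks.

Biochemical models with mass-action kinetics are polynomial dynamical
systems

$$\frac{dx_i}{dt} = \sum_j k_j\, S_{ij}\, x^{\alpha_j},$$

whose parameters are often known only by order of magnitude.  Writing
every quantity as a power of a small parameter $\varepsilon$
($k_j \approx \varepsilon^{\gamma_j}$, $x_i = \bar x_i\,\varepsilon^{a_i}$,
larger order = smaller quantity), each rate monomial gets the integer
degree $\mu_j = \gamma_j + \langle a, \alpha_j\rangle$, and a vector of
concentration orders $a$ is a **tropical equilibration** when, for every
species, the dominant production balances the dominant consumption:

$$\min_{j:\,S_{ij}>0} \mu_j \;=\; \min_{j:\,S_{ij}<0} \mu_j
  \qquad \text{for all } i .$$

Solving this min-plus system identifies the fast variables, the dominant
terms, and hence the reduced (tropically truncated) models and their
fast/slow timescale hierarchy.  `tropicaleq` solves it exactly, as a
finite-domain constraint problem over integer orders with reified
minimum-with-count constraints, dichotomic domain bisection, and
iterative domain expansion — and then derives the truncated systems,
timescale ordering, and the conserved "pools" of the fast dynamics.

It is aimed at modellers who want a systematic, exhaustive alternative to
hand-made quasi-steady-state / quasi-equilibrium arguments, on models
read from SBML (Level 2/3, polynomial kinetics) or a plain-text reaction
format.

## What is in the box

* `read_sbml()`, `parse_reaction_text()` — model input, with a
  distinguishable rejection of non-polynomial kinetic laws.
* `build_odes()` — the signed-monomial ODE representation and coefficient
  orders (`parameter_order()`).
* `find_invariants()`, `attach_constants()` — minimal semi-positive
  conservation laws (P-invariants) and the orders of their conserved
  totals.
* `build_problem()`, `solve_all()`, `solve_with_expansion()` — the
  constraint solver (complete within its search box; every answer is
  re-verified by direct degree evaluation).
* `classify_solution()`, `group_branches()`, `tropical_branches()` —
  dominance signatures and branch structure, including partial
  equilibrations.
* `truncate_system()`, `order_timescales()`, `find_new_pools()` — model
  reduction at an equilibration.
* `tropicalize()` — the one-call analysis returning a classed object with
  `print()`, `summary()` and `plot()` methods.
* `run_model()`, `batch_models()` and a thin CLI
  (`inst/cli/tropicalize.R`) for per-model and per-directory JSON
  reports.
* `grid_equilibrations()` — exhaustive grid reference for small systems,
  plus seeded fixtures (`michaelis_menten_*()`, `random_network()`).

## Worked example

The enzymatic mechanism S + E ⇌ ES → P + E with
$k_1 = 1$, $k_{-1} = 1$, $k_2 = 0.1$ and total enzyme $e_0 = 0.1$
(orders $\gamma_1 = \gamma_{-1} = 0$, $\gamma_2 = 1$, $\gamma_e = 1$ at
$\varepsilon = 0.1$):

```r
library(tropicaleq)
fit <- tropicalize(michaelis_menten_full(gamma1 = 0, gamma_rev = 0,
                                         gamma2 = 1, gamma_e = 1),
                   reduce = TRUE)
summary(fit)
#> Tropical equilibration analysis
#>   4 species, 2 conservation law(s), epsilon = 0.1
#>   complete equilibrations: 4 (domain [-2, 2])
#>   branches: 2
#>   excluded variables: x4
#>
#> System:
#> Polynomial ODE system (4 species, epsilon = 0.1)
#>   dx1/dt = +x2 -x1*x3
#>   dx2/dt = +x1*x3 -1.1*x2
#>   dx3/dt = +1.1*x2 -x1*x3
#>   dx4/dt = +0.1*x2
#> Conservation laws:
#>   x2 + x3 = 0.1 (order kappa = 1)
#>   x1 + x2 + x4 = 1 (order kappa = 0)
#> 2 branch(es) of tropical equilibrations
#>   branch 1 (3 points): equilibrated {x1, x2, x3}; rep x1=0, x2=1, x3=1, x4=1
#>   branch 2 (1 points): equilibrated {x1, x2, x3}; rep x1=1, x2=2, x3=1, x4=0
#>
#> Truncated systems at branch representatives:
#> Tropically truncated system at orders x1=0, x2=1, x3=1, x4=1
#>   dx1/dt = +x2 -x1*x3   [exponent 1]
#>   dx2/dt = +x1*x3 -x2   [exponent 0]
#>   dx3/dt = +x2 -x1*x3   [exponent 0]
#>   dx4/dt = +0.1*x2   [exponent 1]
#> ...
```

Reading the output: the substrate, complex and enzyme all equilibrate
(the product x4 has a production-only equation and is excluded); the four
order vectors found in the default box split into two branches — the two
conservation laws pin the enzyme pool to order $\kappa = 1$ and the
substrate/product pool to order $\kappa = 0$, and the two branches differ
in which law member carries the minimum.  In each truncated system the
merged complex-consumption coefficient $(k_{-1}+k_2)$ has been cut back to
its dominant part $k_{-1}$, and the bracketed timescale exponents
$\mu_{i,\min} - a_i$ rank the variables from fast (small) to slow
(large).

The same analysis from a file, on the command line:

```sh
Rscript inst/cli/tropicalize.R solve inst/extdata/mm.txt --reduce
Rscript inst/cli/tropicalize.R batch models/ --format tsv -o summary.tsv
```

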