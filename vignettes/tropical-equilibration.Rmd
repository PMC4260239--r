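---
title: "Tropical equilibration of mass-action networks as a constraint problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tropical equilibration of mass-action networks as a constraint problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tropicaleq)
```

## The model

A mass-action reaction network over species $x_1,\dots,x_n$ induces the
polynomial differential system

$$\frac{dx_i}{dt} \;=\; \sum_j k_j\, S_{ij}\, x^{\alpha_j},$$

where $\alpha_j$ is the kinetic exponent vector of reaction $j$, $S_{ij}$
the stoichiometric matrix and $k_j > 0$ the rate constants.  When
parameters are known only up to order of magnitude it is natural to write
them as powers of a small parameter $\varepsilon$: a quantity $k$ has
integer *order* $\gamma = \operatorname{round}(\log k / \log \varepsilon)$,
so that $k \approx \varepsilon^{\gamma}$ and *larger orders mean smaller
quantities*.  Assigning unknown orders $a_i$ to the concentrations and
rescaling $x_i = \bar x_i\,\varepsilon^{a_i}$ turns every monomial of
every equation into an affine integer form, its *degree*

$$\mu_j \;=\; \gamma_j + \langle a, \alpha_j \rangle .$$

For small $\varepsilon$ the monomial of smallest degree dominates an
equation.  A fast variable can only stay bounded if its dominant
production and consumption balance, which at the level of orders reads,
for every species $i$,

$$\min_{j\,:\,S_{ij} > 0} \mu_j \;=\; \min_{j\,:\,S_{ij} < 0} \mu_j .$$

An integer vector $a$ satisfying this min-plus system is a *tropical
equilibration*.  It is a necessary condition for eliminating fast
variables, and the package's job is to enumerate all such vectors and
derive the corresponding reduced (truncated) models.

Semi-positive conservation laws $b \ge 0$, $b^{\mathsf T} S = 0$
(P-invariants of the reaction network) constrain the rescaling further:
if $\sum_i b_i x_i = c$ along trajectories, the smallest member order must
match the order $\kappa = \operatorname{round}(\log c/\log\varepsilon)$ of
the conserved total, i.e. $\min_{i : b_i > 0} (\operatorname{ord}(b_i) + a_i) = \kappa$.

## The constraint encoding

The equilibration system is nonlinear in the min-plus sense, and the
number of candidate dominant-monomial pairings grows exponentially with
the network size.  Instead of enumerating pairings symbolically, the
package poses a finite-domain constraint problem:

* one integer decision variable $a_i$ per species that occurs in any
  equation or law (species with empty equations and no occurrences are
  inert and get no variable);
* per equilibrated species one shared minimum variable $M_i$ with two
  minimum-with-count constraints, `min(positive degrees) = M_i` and
  `min(negative degrees) = M_i`, so the overall minimum is attained at
  least twice with opposite signs;
* per conservation law, `min(member degrees) = kappa` with the constant
  $\kappa$.

The minimum-with-count constraint is implemented with reified equalities:
conceptually one boolean $B_j \Leftrightarrow (M = f_j)$ per affine form,
with $\sum_j B_j \ge c_{\min}$.  Propagation runs on interval (bounds)
domains and flows in all directions: $M$ is capped by the least upper
bound of the forms, every form is floored by $M$'s lower bound (which
tightens individual variables), and when only $c_{\min}$ forms can still
attain the minimum they are forced onto it.  Fixing $M$ therefore prunes
variables of candidate forms, and forms proven strictly above $M$ transfer
the count obligation to the remaining candidates — the behaviour the
reified encoding exists for.

Bounds propagation alone is incomplete, so the solver interleaves it with
*dichotomic search*: the first unfixed variable's interval is bisected at
its midpoint and both halves are explored, with no variable-selection
heuristic.  Every full assignment is re-verified by direct degree
evaluation before being reported, so reported solutions are sound
independently of the propagation code path.  Completeness within the
search box is checked in the test suite against exhaustive grid
enumeration on small random networks.

Orders are searched in a symmetric box $[-D, D]^n$.  The default schedule
starts at $D = 2$ and doubles the half-width ($4, 8, \dots$) whenever the
current box contains no solution, up to $D = 128$ — with
$\varepsilon = 0.1$ this spans magnitudes between $10^{-128}$ and
$10^{128}$, far beyond what concentrations in practice realize.  Solutions
outside the final box are knowingly missed; `boundary_hit` in the result
records whether solutions touch the box edge, and the enumeration cap
(default $10^6$) together with that flag is the practical detector of
under-constrained problems with unbounded solution families.

## Branches and partial equilibrations

Solutions organize into *branches*: maximal families sharing the same
dominance structure.  The package keys each solution by a signature made
of (i) the set of equilibrated species, (ii) the active (minimal-degree)
monomials of every equation, and (iii) the active members of every
conservation law.  Two subtleties required design decisions:

* **Vertices.**  Where two half-lines of solutions meet, the junction
  point carries a strictly larger active set than either neighbour.  Such
  a class is merged into an adjacent branch whose signature it dominates
  componentwise (deterministically, into the first dominated class in
  sorted signature order).  Without this rule every tripod vertex of a
  tropical curve would spuriously count as its own branch.
* **Partial equilibrations.**  In some parameter regimes the complete
  problem (all two-signed equations balanced) is infeasible, yet families
  balancing a subset of the equations still organize the dynamics and are
  exactly what quasi-stationarity-type reductions use.
  `tropical_branches()` therefore unions the complete problem's solutions
  with those of each single-species equilibration problem (conservation
  laws always enforced) before grouping.  For the classic enzymatic
  mechanism this reproduces the known classification: two branches when
  dissociation dominates catalysis, four in the opposite regime, and six
  distinct signatures for the unreduced three-variable system with its
  enzyme-conservation constraint.  Law-member activity must be part of
  the signature: it is the only thing separating the two all-equilibrated
  branches of the unreduced system.

`min_count` defaults to 2 attained minima per equation, which the
shared-$M$ encoding already implies (one positive and one negative).
Values above 2 post an additional count constraint over the combined
monomial list, for settings away from steady state where a single
balancing pair is not enough.

## Truncation, timescales, pools

At a given equilibration the *tropically truncated* system keeps, per
equation, exactly the monomials attaining the minimal degree.  One wrinkle
comes from the canonical merged form of the equations: monomials with
identical sign and exponents are merged (their magnitudes summed) before
order computation, so a merged coefficient such as $(k_{-1} + k_2)x_2$ can
contain parts of different orders.  Each monomial therefore remembers its
contributing components, and truncation keeps only the minimal-order
components of a retained monomial — the dominated part of the coefficient
joins the dropped terms.  This is what makes the truncated systems match
the classical quasi-equilibrium and quasi-stationarity reductions
coefficient for coefficient, and it is essential for pool detection.

Variables are ordered by the timescale exponents $\mu_{i,\min} - a_i$ of
the rescaled equations (smaller = faster).  For the enzymatic mechanism
this recovers the textbook conditions: the complex is the fast variable
exactly when $\gamma_1 + \gamma_e > \gamma_2$ (low enzyme), and the
substrate is faster in the opposite, high-enzyme regime.

The truncated fast dynamics can conserve linear combinations that the full
system does not — *pools*, which are supplementary slow variables.
`find_new_pools()` computes semi-positive integer kernels of the truncated
species-by-monomial coefficient matrix (each distinct monomial one
column — truncation acts on monomials, not reactions), discards those that
are already conservation laws of the full system, and reports each pool
with its residual driving monomials: the signed sum of the previously
dominated terms weighted by the pool coefficients, which is the pool's
slow derivative.  For the quasi-equilibrium branch of the enzymatic
mechanism this yields $z = x_1 + x_2$ driven by $-k_2 x_2$.  The further
symbolic step of solving the fast equilibrium and substituting (producing
a closed-form slow ODE for $z$) is deliberately out of scope; the residual
monomials and their orders carry the information needed to verify the
fast/slow split.

Permanency — boundedness of the rescaled concentrations, which a
truncation needs in order to define a valid reduced model — is *not*
checked.  Branches that equilibrate but converge to a boundary are still
reported, with the timescale data a modeller needs to discard them.

## Conservation-law computation

Any method producing the generating set of minimal semi-positive
invariants would do; the one implemented is the classical Fourier–Motzkin
style semiflow computation on the tableau $[\,I \mid S\,]$: columns of $S$ are annulled
one by one by nonnegative row combinations, rows are gcd-reduced (jointly
over both tableau halves), and rows whose support strictly contains
another row's support are pruned at every step, yielding the
minimal-support generating set.  Row growth is capped at 8192 (with a
warning) — generous for desk-scale networks, not meant for genome-scale
stoichiometries.  For systems defined directly by their equations rather
than by reactions, the same computation runs on the signed
species-by-monomial coefficient matrix with columns scaled to integers by
continued-fraction rationalization (denominator limit $10^6$, tolerance
$10^{-9}$).  Laws can also be supplied in a side-car JSON/TSV file,
overriding computation.

## Numerical and degenerate-input choices

* **Rounding.**  Orders use round-half-away-from-zero, centralized in
  `parameter_order()`.  Rational orders with a small common denominator
  $q$ are supported by pre-multiplying the log-ratio by $q$ (default
  $q = 1$, integers only, matching the finite-domain variables).
* **Merging.**  Duplicate monomials merge *before* order computation;
  exact positive/negative cancellation drops the monomial and can render
  a species inert.
* **Degenerate inputs.**  Zero-rate reactions are dropped with a warning;
  species with empty or single-signed equations are excluded from
  equilibration constraints and listed in `excluded_variables` ("complete
  equilibration" means all non-excluded species equilibrated);
  conservation laws with zero initial total have no defined constant
  order and are dropped with a warning; a model in which nothing can
  equilibrate raises a distinguishable condition rather than an empty
  result.
* **SBML.**  A kinetic law is accepted iff, after numeric substitution of
  parameters, compartments and boundary species, it expands to a
  polynomial in the dynamic species; each expanded term becomes one rate
  monomial (negative terms flip the net stoichiometry, as for the reverse
  direction of a reversible law).  Events are ignored with a warning;
  non-constant rules feeding a kinetic law trigger the non-polynomial
  rejection, as do compartments of differing size (folding their volumes
  into reaction-level constants would break integer stoichiometry).

## What the built-in fixtures do and do not show

The fixture generators define the study conditions for the test suite.
The enzymatic-mechanism fixtures use rate constants that are exact powers
$\varepsilon^{\gamma}$ with unit prefactors, so coefficient orders are
exact and solver behaviour is tested separately from rounding behaviour;
the two parameter regimes used throughout
($\gamma = (0, 0, 1)$ with $\gamma_e = 1$, and $\gamma = (0, 2, 0)$ with
$\gamma_e = 1$) realize the two qualitative placements of the
dissociation/catalysis orders.  Random networks are bounded — at most
bimolecular reactant sides, stoichiometries in $\{1, 2\}$, coefficient
orders uniform in a small range — and reproducible from a seed.

These fixtures emulate the *structure* of biochemical models (signed
monomial equations, conservation laws, well-separated magnitudes), not
their biology: topologies are not realistic, kinetics are pure mass
action, and sizes stay at desk scale (boxes $[-6,6]$, fifty random
networks with up to four species in the exactness suite — sizes chosen so
exhaustive grid enumeration remains a feasible oracle).  Passing tests
therefore certify the algebra and the solver's completeness-in-a-box, not
performance or SBML coverage on repository-scale models; the batch
machinery exists for such screens but its published per-model counts can
only be reproduced with the corresponding model files present.

## Known limitations

Partial-equilibration enumeration is exhaustive over single equations,
not a Max-CSP maximization of the equilibrated set; solutions with
rational, non-integer orders are only reachable through the $q$
pre-scaling; infinite solution families are detected, not described
symbolically; and no permanency or validity-domain analysis is performed
on the reported truncations.
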