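## Built-in fixture generators: the Michaelis-Menten mechanism at
## prescribed parameter orders, and seeded random mass-action networks.
## Rate constants are exact powers epsilon^gamma (unit prefactors), so
## coefficient orders are exact and independent of rounding behaviour.

#' Michaelis-Menten fixtures at prescribed parameter orders
#'
#' The enzymatic mechanism S + E <-> ES -> P + E with rate constants
#' \eqn{k_1 = \epsilon^{\gamma_1}}, \eqn{k_{-1} = \epsilon^{\gamma_{-1}}},
#' \eqn{k_2 = \epsilon^{\gamma_2}}, total enzyme \eqn{e_0 = \epsilon^{\gamma_e}}
#' and total substrate \eqn{s_0 = \epsilon^{\gamma_s}}.
#'
#' `michaelis_menten_full()` returns the 4-species, 3-reaction network
#' (species x1 = S, x2 = ES, x3 = E, x4 = P) whose ODEs are
#' \deqn{x_1' = -k_1 x_1 x_3 + k_{-1} x_2, \quad
#'       x_2' = k_1 x_1 x_3 - (k_{-1} + k_2) x_2, \quad
#'       x_3' = -x_2', \quad x_4' = k_2 x_2.}
#'
#' `michaelis_menten_reduced()` returns the 2-variable polynomial system
#' obtained after eliminating E and P by the conservation laws
#' (\eqn{x_2 + x_3 = e_0}):
#' \deqn{x_1' = -k_1 x_1 (e_0 - x_2) + k_{-1} x_2, \quad
#'       x_2' = k_1 x_1 (e_0 - x_2) - (k_{-1} + k_2) x_2.}
#'
#' `michaelis_menten_conserved()` returns the unreduced 3-variable system
#' (P dropped, its equation being pure production) together with its
#' conservation law \eqn{x_2 + x_3 = e_0}, the setting in which the
#' equilibration problem carries an explicit conservation-law constraint.
#'
#' @param gamma1,gamma_rev,gamma2 integer orders of k1, k-1, k2.
#' @param gamma_e,gamma_s integer orders of the total enzyme and substrate.
#' @param epsilon small parameter in (0, 1).
#' @return `michaelis_menten_full()` a [reaction_network()];
#'   `michaelis_menten_reduced()` a [polynomial_system()];
#'   `michaelis_menten_conserved()` a list with elements `system` and
#'   `laws`.
#' @export
michaelis_menten_full <- function(gamma1 = 0L, gamma_rev = 0L, gamma2 = 1L,
                                  gamma_e = 1L, gamma_s = 0L, epsilon = 0.1) {
  k <- function(g) epsilon^g
  reaction_network(
    species = c("x1", "x2", "x3", "x4"),
    reactions = list(
      reaction(c(x1 = 1, x3 = 1), c(x2 = 1), k(gamma1), id = "bind"),
      reaction(c(x2 = 1), c(x1 = 1, x3 = 1), k(gamma_rev), id = "unbind"),
      reaction(c(x2 = 1), c(x3 = 1, x4 = 1), k(gamma2), id = "cat")),
    init = c(x1 = k(gamma_s), x3 = k(gamma_e)))
}

#' @rdname michaelis_menten_full
#' @export
michaelis_menten_reduced <- function(gamma1 = 0L, gamma_rev = 0L, gamma2 = 1L,
                                     gamma_e = 1L, epsilon = 0.1) {
  k <- function(g) epsilon^g
  ## generalized reactions realizing the eliminated-variable right-hand
  ## sides: kinetic exponents differ from the net stoichiometry
  net <- reaction_network(
    species = c("x1", "x2"),
    reactions = list(
      reaction(c(x1 = 1), c(x2 = 1), k(gamma1) * k(gamma_e),
               exponents = c(x1 = 1), id = "bind_free"),
      reaction(c(x2 = 1), c(x1 = 1), k(gamma1),
               exponents = c(x1 = 1, x2 = 1), id = "bind_occupied"),
      reaction(c(x2 = 1), c(x1 = 1), k(gamma_rev),
               exponents = c(x2 = 1), id = "unbind"),
      reaction(c(x2 = 1), NULL, k(gamma2),
               exponents = c(x2 = 1), id = "cat")))
  build_odes(net, epsilon)
}

#' @rdname michaelis_menten_full
#' @export
michaelis_menten_conserved <- function(gamma1 = 0L, gamma_rev = 0L,
                                       gamma2 = 1L, gamma_e = 1L,
                                       gamma_s = 0L, epsilon = 0.1) {
  k <- function(g) epsilon^g
  net <- reaction_network(
    species = c("x1", "x2", "x3"),
    reactions = list(
      reaction(c(x1 = 1, x3 = 1), c(x2 = 1), k(gamma1), id = "bind"),
      reaction(c(x2 = 1), c(x1 = 1, x3 = 1), k(gamma_rev), id = "unbind"),
      reaction(c(x2 = 1), c(x3 = 1), k(gamma2), id = "cat")),
    init = c(x1 = k(gamma_s), x3 = k(gamma_e)))
  system <- build_odes(net, epsilon)
  laws <- attach_constants(find_invariants(net), net, epsilon)
  list(system = system, laws = laws)
}

#' Seeded random mass-action network
#'
#' Reproducible generator for solver cross-checks: at most bimolecular
#' reactant sides with stoichiometries in {1, 2}, product sides of one or
#' two species with stoichiometries in {1, 2}, and rate constants
#' \eqn{\epsilon^\gamma} with \eqn{\gamma} drawn uniformly from
#' `order_range`.  Initial concentrations are \eqn{\epsilon^u} with
#' \eqn{u} uniform in 0..2.  The caller's RNG state is left untouched.
#'
#' @param n_species,n_reactions positive integers.
#' @param order_range integer vector (range) of coefficient orders.
#' @param seed integer seed; a fixed seed gives a byte-identical network.
#' @param epsilon small parameter used for the rate-constant scale.
#' @return a [reaction_network()].
#' @export
random_network <- function(n_species, n_reactions, order_range = -3:3,
                           seed = 1L, epsilon = 0.1) {
  stopifnot(n_species >= 1, n_reactions >= 1)
  species <- paste0("s", seq_len(n_species))
  with_seed(seed, {
    side <- function() {
      n_sp <- sample(1:min(2, n_species), 1)
      picks <- sample(species, n_sp)
      st <- if (n_sp == 1) sample(1:2, 1) else rep(1L, 2)
      stats::setNames(as.integer(st), picks)
    }
    reactions <- lapply(seq_len(n_reactions), function(j) {
      gamma <- sample(order_range, 1)
      reaction(side(), side(), epsilon^gamma, id = paste0("r", j))
    })
    init <- stats::setNames(epsilon^sample(0:2, n_species, replace = TRUE),
                            species)
    reaction_network(species, reactions, init)
  })
}
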