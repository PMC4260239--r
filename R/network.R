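#' Construct a mass-action reaction network
#'
#' A reaction network is an ordered list of species, their initial
#' concentrations, and a list of reactions.  Each reaction has integer
#' reactant and product stoichiometries and a positive rate constant; the
#' reaction rate is \eqn{k_j \prod_i x_i^{\alpha_{ji}}} where by default the
#' kinetic exponents \eqn{\alpha_{ji}} equal the reactant stoichiometry
#' (mass-action kinetics).  A reaction may carry an explicit `exponents`
#' vector instead, which is how expanded polynomial (non-elementary) SBML
#' rate laws are represented: the net stoichiometry stays integral while the
#' kinetic exponents come from the expanded monomial.
#'
#' @param species character vector of species identifiers (order is kept).
#' @param reactions list of reactions as produced by [reaction()].
#' @param init named numeric vector of nonnegative initial concentrations;
#'   species absent from `init` start at 0.
#' @return an object of class `reaction_network`.
#' @seealso [parse_reaction_text()], [read_sbml()], [build_odes()]
#' @export
reaction_network <- function(species, reactions = list(), init = numeric()) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicated species identifiers")
  init_full <- stats::setNames(numeric(length(species)), species)
  if (length(init)) {
    unknown <- setdiff(names(init), species)
    if (length(unknown)) stop("initial concentration for unknown species: ",
                              paste(unknown, collapse = ", "))
    if (any(init < 0)) stop("initial concentrations must be nonnegative")
    init_full[names(init)] <- init
  }
  kept <- list()
  for (r in reactions) {
    refd <- unique(c(names(r$reactants), names(r$products), names(r$exponents)))
    missing <- setdiff(refd, species)
    if (length(missing)) stop("reaction references unknown species: ",
                              paste(missing, collapse = ", "))
    if (r$k == 0) { warning("dropping zero-rate reaction ", r$id); next }
    if (r$k < 0) stop("rate constant must be positive in reaction ", r$id)
    kept[[length(kept) + 1L]] <- r
  }
  structure(list(species = species, init = init_full, reactions = kept),
            class = "reaction_network")
}

#' @param reactants,products named nonnegative integer vectors (stoichiometry).
#' @param k positive rate constant.
#' @param exponents optional named nonnegative integer vector of kinetic
#'   exponents; defaults to `reactants`.
#' @param id reaction identifier used in messages.
#' @rdname reaction_network
#' @export
reaction <- function(reactants, products, k, exponents = NULL, id = NULL) {
  chk <- function(v, what) {
    if (is.null(v)) return(stats::setNames(integer(), character()))
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      stop(what, " stoichiometry must be a named vector")
    if (any(v < 0) || any(!is_wholenumber(v)))
      stop(what, " stoichiometry must be nonnegative integers")
    v <- v[v > 0]
    stats::setNames(as.integer(round(v)), names(v))
  }
  structure(list(reactants = chk(reactants, "reactant"),
                 products = chk(products, "product"),
                 k = as.numeric(k),
                 exponents = if (!is.null(exponents)) chk(exponents, "exponent"),
                 id = id %||% "r"),
            class = "reaction")
}

n_species <- function(net) length(net$species)
n_reactions <- function(net) length(net$reactions)

#' Stoichiometric matrix of a network
#'
#' Integer matrix with one row per species and one column per reaction,
#' entries \eqn{S_{ij} = \beta_{ji} - \alpha_{ji}}.
#'
#' @param network a `reaction_network`.
#' @return integer matrix (species x reactions).
#' @export
stoichiometric_matrix <- function(network) {
  S <- matrix(0L, n_species(network), n_reactions(network),
              dimnames = list(network$species,
                              vapply(network$reactions, `[[`, "", "id")))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    S[names(r$products), j] <- S[names(r$products), j] + r$products
  }
  S
}

#' Parse the plain-text reaction format
#'
#' One reaction per line:
#' `[coef] SPECIES {+ [coef] SPECIES}* -> [coef] SPECIES {+ ...}* ; k=FLOAT`.
#' Either side may be empty (pure production or degradation).  `#` starts a
#' comment; `init: SPECIES=FLOAT` lines set initial concentrations.
#' Duplicate species on one side accumulate their coefficients.
#'
#' @param text a character scalar (possibly multi-line) or vector of lines.
#' @return a [reaction_network()].
#' @export
parse_reaction_text <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  species <- character(); init <- numeric(); reactions <- list()
  parse_side <- function(s, lineno) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(integer(), character()))
    out <- stats::setNames(integer(), character())
    for (term in strsplit(s, "+", fixed = TRUE)[[1]]) {
      term <- trimws(term)
      m <- regmatches(term, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$", term))[[1]]
      if (!length(m)) stop("syntax error in species term '", term, "' at line ", lineno)
      coef <- if (nzchar(m[2])) as.integer(m[2]) else 1L
      sp <- m[3]
      out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + coef
    }
    out
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (grepl("^init\\s*:", line)) {
      body <- sub("^init\\s*:", "", line)
      m <- regmatches(body, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-+0-9.eE]+)\\s*$", body))[[1]]
      if (!length(m)) stop("syntax error in init line ", i)
      init[m[2]] <- as.numeric(m[3])
      species <- union(species, m[2])
      next
    }
    parts <- strsplit(line, ";", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("syntax error (expected '; k=...') at line ", i)
    km <- regmatches(parts[2], regexec("^\\s*k\\s*=\\s*([-+0-9.eE]+)\\s*$", parts[2]))[[1]]
    if (!length(km)) stop("syntax error in rate constant at line ", i)
    k <- as.numeric(km[2])
    if (is.na(k) || k <= 0) stop("nonpositive rate constant at line ", i)
    sides <- strsplit(parts[1], "->", fixed = TRUE)[[1]]
    if (length(sides) > 2) stop("syntax error (multiple '->') at line ", i)
    if (length(sides) == 1) sides <- c(sides, "")
    lhs <- parse_side(sides[1], i); rhs <- parse_side(sides[2], i)
    species <- union(species, union(names(lhs), names(rhs)))
    reactions[[length(reactions) + 1L]] <-
      reaction(lhs, rhs, k, id = paste0("r", length(reactions) + 1L))
  }
  reaction_network(species, reactions, init)
}

#' @param path path to a file in the plain-text reaction format.
#' @rdname parse_reaction_text
#' @export
read_reaction_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_reaction_text(readLines(path, warn = FALSE))
}

#' Render a network in the plain-text reaction format
#'
#' Inverse of [parse_reaction_text()]: `parse_reaction_text(render_reaction_text(net))`
#' reproduces the species set, stoichiometries and rate constants.
#'
#' @param network a `reaction_network`.
#' @return a character scalar.
#' @export
render_reaction_text <- function(network) {
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(v > 1L, paste(v, names(v)), names(v)), collapse = " + ")
  }
  lines <- character()
  nz <- network$init[network$init > 0]
  lines <- c(lines, sprintf("init: %s=%.17g", names(nz), nz))
  for (r in network$reactions)
    lines <- c(lines, sprintf("%s -> %s ; k=%.17g",
                              side(r$reactants), side(r$products), r$k))
  paste(lines, collapse = "\n")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions\n",
              n_species(x), n_reactions(x)))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  side <- function(v) if (length(v))
    paste(ifelse(v > 1L, paste(v, names(v)), names(v)), collapse = " + ") else "0"
  for (r in x$reactions) {
    tag <- if (!is.null(r$exponents)) " [explicit kinetic exponents]" else ""
    cat(sprintf("  %s: %s -> %s ; k=%g%s\n", r$id, side(r$reactants),
                side(r$products), r$k, tag))
  }
  invisible(x)
}
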