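## Semi-positive conservation laws (P-invariants): integer vectors b >= 0
## with b' S = 0.  Computed by the classical Fourier-Motzkin style semiflow
## algorithm on [I | S], keeping minimal-support rows.

semiflows <- function(S, max_rows = 8192L) {
  n <- nrow(S)
  B <- diag(1L, n)
  T <- S
  storage.mode(T) <- "double"
  for (j in seq_len(ncol(S))) {
    col <- T[, j]
    zero <- which(col == 0)
    pos <- which(col > 0); neg <- which(col < 0)
    newB <- B[zero, , drop = FALSE]
    newT <- T[zero, , drop = FALSE]
    if (length(pos) && length(neg)) {
      for (i in pos) for (k in neg) {
        row_b <- abs(col[k]) * B[i, ] + col[i] * B[k, ]
        row_t <- abs(col[k]) * T[i, ] + col[i] * T[k, ]
        g <- gcd_vec(c(row_b, row_t))   # keep B and T in step
        if (g > 1) { row_b <- row_b / g; row_t <- row_t / g }
        newB <- rbind(newB, row_b)
        newT <- rbind(newT, row_t)
      }
    }
    if (nrow(newB) > max_rows) {
      warning("semiflow computation truncated at ", max_rows, " rows")
      newB <- newB[seq_len(max_rows), , drop = FALSE]
      newT <- newT[seq_len(max_rows), , drop = FALSE]
    }
    ## prune rows whose support strictly contains another row's support,
    ## and duplicated rows
    if (nrow(newB) > 1) {
      supp <- newB > 0
      keep <- rep(TRUE, nrow(newB))
      ord <- order(rowSums(supp))
      for (ii in seq_along(ord)) {
        a <- ord[ii]
        if (!keep[a]) next
        for (jj in seq_along(ord)) {
          b <- ord[jj]
          if (a == b || !keep[b]) next
          if (all(supp[b, ] >= supp[a, ]) && any(supp[b, ] != supp[a, ]))
            keep[b] <- FALSE
          else if (all(supp[b, ] == supp[a, ]) && b > a &&
                   identical(newB[a, ], newB[b, ]))
            keep[b] <- FALSE
        }
      }
      newB <- newB[keep, , drop = FALSE]
      newT <- newT[keep, , drop = FALSE]
    }
    B <- newB; T <- newT
  }
  if (!nrow(B)) return(list())
  B <- unique(B)
  out <- lapply(seq_len(nrow(B)), function(i)
    stats::setNames(as.integer(B[i, ]), rownames(S)))
  out[order(vapply(out, paste, "", collapse = ","), method = "radix")]
}

#' Semi-positive conservation laws of a system
#'
#' Returns a generating set of minimal-support semi-positive integer
#' left-kernel vectors \eqn{b \ge 0}, \eqn{b^T S = 0} (P-invariants).  For
#' a system built from a network, `S` is the reaction stoichiometric
#' matrix; for a system defined directly by its equations, the signed
#' species-by-monomial coefficient matrix is used instead (columns scaled
#' to integers).  An empty list is a valid result (no semi-positive vector
#' in the left kernel).
#'
#' @param x a `polynomial_system`, `reaction_network`, or numeric matrix
#'   (species in rows).
#' @return list of named nonnegative integer coefficient vectors with
#'   gcd 1, in a deterministic order.
#' @export
find_invariants <- function(x) {
  S <- if (is.matrix(x)) x
  else if (inherits(x, "reaction_network")) stoichiometric_matrix(x)
  else if (inherits(x, "polynomial_system")) {
    if (!is.null(x$stoichiometric_matrix)) x$stoichiometric_matrix
    else monomial_matrix(x)
  } else stop("cannot extract a stoichiometric structure from ", class(x)[1])
  if (is.null(rownames(S))) rownames(S) <- paste0("s", seq_len(nrow(S)))
  if (!is.integer(S) && any(!is_wholenumber(S))) S <- integerize_columns(S)
  laws <- semiflows(S)
  Filter(function(b) any(b > 0), laws)
}

#' Attach conserved constants and their orders to invariants
#'
#' For each coefficient vector \eqn{b}, the conserved constant is the value
#' of \eqn{\sum_i b_i x_i} at the initial concentrations and its order is
#' \eqn{\kappa = \mathrm{round}(\log c / \log \epsilon)}.  Laws whose
#' initial total is zero have no defined order and are dropped with a
#' warning.
#'
#' @param laws list of named coefficient vectors (from [find_invariants()])
#'   or of `conservation_law` objects.
#' @param network a [reaction_network()] supplying initial concentrations,
#'   or a named numeric vector of initial concentrations.
#' @param epsilon small parameter in (0, 1).
#' @param q order denominator pre-multiplier.
#' @return list of `conservation_law` objects with fields `coefficients`,
#'   `constant` and `kappa`.
#' @export
attach_constants <- function(laws, network, epsilon = 0.1, q = 1L) {
  init <- if (inherits(network, "reaction_network")) network$init else network
  out <- list()
  for (b in laws) {
    if (inherits(b, "conservation_law")) b <- b$coefficients
    total <- sum(b * init[names(b)])
    if (is.na(total)) stop("initial concentration missing for a law member")
    if (total <= 0) {
      warning("dropping conservation law with zero initial total: ",
              paste(names(b)[b > 0], collapse = "+"))
      next
    }
    out[[length(out) + 1L]] <- conservation_law(b, total, epsilon, q)
  }
  out
}

#' @param coefficients named nonnegative integer vector b.
#' @param constant positive conserved total c.
#' @rdname attach_constants
#' @export
conservation_law <- function(coefficients, constant, epsilon = 0.1, q = 1L) {
  g <- gcd_vec(coefficients)
  if (g > 1) coefficients <- coefficients / g
  structure(list(coefficients = coefficients[coefficients > 0],
                 constant = constant,
                 kappa = parameter_order(constant, epsilon, q)),
            class = "conservation_law")
}

#' @export
print.conservation_law <- function(x, ...) {
  b <- x$coefficients
  cat(sprintf("%s = %g (order kappa = %d)\n",
              paste(ifelse(b == 1L, names(b), paste0(b, "*", names(b))),
                    collapse = " + "),
              x$constant, x$kappa))
  invisible(x)
}

#' Read conservation laws from a side-car file
#'
#' Laws may be supplied externally, overriding computation.  JSON format:
#' an array of objects `{"coefficients": {"A": 1, "B": 2}, "constant": 1.0}`
#' (constant optional when the network's initial concentrations determine
#' it).  TSV format: columns `law`, `species`, `coefficient` and optionally
#' `constant` (repeated per row of one law).
#'
#' @param path path to a `.json` or `.tsv` file.
#' @param epsilon,q passed to [conservation_law()] when constants are given.
#' @return list of `conservation_law` objects (with constants) or plain
#'   coefficient vectors (without).
#' @export
read_laws <- function(path, epsilon = 0.1, q = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    lapply(recs, function(r) {
      b <- unlist(r$coefficients)
      if (is.null(r$constant)) b
      else conservation_law(b, r$constant, epsilon, q)
    })
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    lapply(split(tab, tab$law), function(d) {
      b <- stats::setNames(as.integer(d$coefficient), d$species)
      if ("constant" %in% names(d) && !any(is.na(d$constant)))
        conservation_law(b, d$constant[[1]], epsilon, q)
      else b
    })
  }
}
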