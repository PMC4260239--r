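`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

## gcd of an integer vector (0 for the all-zero vector)
gcd_vec <- function(v) Reduce(gcd2, abs(v), accumulate = FALSE)

## Continued-fraction rational approximation p/q with q <= maxden.
rationalize <- function(x, maxden = 1e6, tol = 1e-9) {
  if (abs(x) < tol) return(c(0L, 1L))
  sgn <- sign(x); x <- abs(x)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > maxden) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol * max(1, x)) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(sgn * p1, q1)
}

## Scale the columns of a numeric matrix to (small) integers.
## Returns an integer matrix proportional column-wise to `m`.
integerize_columns <- function(m, maxden = 1e6) {
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    nz <- which(abs(col) > 1e-12)
    if (!length(nz)) next
    scaled <- col / min(abs(col[nz]))
    pq <- vapply(scaled, rationalize, numeric(2), maxden = maxden)
    den <- Reduce(function(a, b) a / gcd2(a, b) * b, pq[2, ], accumulate = FALSE)
    ints <- round(pq[1, ] * den / pq[2, ])
    g <- gcd_vec(ints)
    if (g > 0) ints <- ints / g
    out[, j] <- ints
  }
  storage.mode(out) <- "integer"
  out
}
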