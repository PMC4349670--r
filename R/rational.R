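# Exact rational arithmetic on numerator/denominator pairs stored in doubles.
# Doubles represent integers exactly below 2^53; every operation reduces by the
# gcd and a guard errors out long before that bound can be crossed.

.MAX_EXACT <- 2^52

check_exact <- function(x) {
  if (any(abs(x) >= .MAX_EXACT, na.rm = TRUE)) {
    abort("exact integer arithmetic overflow (magnitude >= 2^52)")
  }
  invisible(x)
}

gcd2 <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

# gcd of a vector, 0 for an all-zero (or empty) vector
gcd_all <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0) return(0)
  g <- x[1]
  for (v in x[-1]) {
    g <- gcd2(g, v)
    if (g == 1) break
  }
  g
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / gcd2(a, b) * b)
}

lcm_all <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0) return(1)
  Reduce(lcm2, x)
}

# vectorized reduce of num/den pairs to canonical form (den > 0, gcd 1)
rat_reduce <- function(num, den) {
  stopifnot(length(num) == length(den))
  if (any(den == 0)) abort("zero denominator")
  sgn <- sign(den)
  num <- num * sgn
  den <- den * sgn
  g <- mapply(gcd2, abs(num), den)
  g[g == 0] <- 1
  check_exact(c(num, den))
  list(num = num / g, den = den / g)
}

rat_add <- function(n1, d1, n2, d2) {
  num <- n1 * d2 + n2 * d1
  den <- d1 * d2
  check_exact(c(num, den))
  rat_reduce(num, den)
}

rat_mul <- function(n1, d1, n2, d2) {
  num <- n1 * n2
  den <- d1 * d2
  check_exact(c(num, den))
  rat_reduce(num, den)
}

# parse "3", "-2", "3/4" into a num/den pair
rat_parse <- function(txt) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^(-?[0-9]+)(?:/([0-9]+))?$", txt))[[1]]
  if (length(m) == 0 || m[1] == "") {
    abort(paste0("malformed rational coefficient: '", txt, "'"))
  }
  num <- as.numeric(m[2])
  den <- if (is.na(m[3]) || m[3] == "") 1 else as.numeric(m[3])
  out <- rat_reduce(num, den)
  c(num = out$num, den = out$den)
}

# reduce an integer vector by its gcd (canonical ray representative)
int_reduce <- function(x) {
  g <- gcd_all(x)
  if (g > 1) x <- x / g
  check_exact(x)
  x
}

# --- exact rational matrix RREF and nullspace ------------------------------
# Matrices are carried as a pair of numeric matrices (numerators N over
# denominators D). Sizes here are tiny (module stoichiometries, oracle
# systems), so plain loops are fine.

rat_rref <- function(N, D) {
  m <- nrow(N)
  n <- ncol(N)
  pivots <- integer(0)
  r <- 1L
  for (cidx in seq_len(n)) {
    if (r > m) break
    # choose first nonzero pivot in column cidx at/under row r
    prow <- which(N[r:m, cidx] != 0)
    if (length(prow) == 0) next
    prow <- prow[1] + r - 1L
    if (prow != r) {
      N[c(r, prow), ] <- N[c(prow, r), ]
      D[c(r, prow), ] <- D[c(prow, r), ]
    }
    # scale pivot row to 1
    pn <- N[r, cidx]
    pd <- D[r, cidx]
    res <- rat_mul(N[r, ], D[r, ], rep(pd, n), rep(pn, n))
    N[r, ] <- res$num
    D[r, ] <- res$den
    # eliminate column cidx from all other rows
    for (i in seq_len(m)) {
      if (i == r || N[i, cidx] == 0) next
      fn <- N[i, cidx]
      fd <- D[i, cidx]
      sub <- rat_mul(N[r, ], D[r, ], rep(-fn, n), rep(fd, n))
      res <- rat_add(N[i, ], D[i, ], sub$num, sub$den)
      N[i, ] <- res$num
      D[i, ] <- res$den
    }
    pivots <- c(pivots, cidx)
    r <- r + 1L
  }
  list(N = N, D = D, pivots = pivots)
}

# exact nullspace of an integer matrix, returned as an integer matrix whose
# columns are gcd-reduced basis vectors (one per free column of the RREF)
int_nullspace <- function(M) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  n <- ncol(M)
  if (n == 0) return(matrix(0, nrow = 0, ncol = 0))
  if (nrow(M) == 0) {
    return(diag(1, n))
  }
  rr <- rat_rref(M, matrix(1, nrow(M), ncol(M)))
  pivots <- rr$pivots
  free <- setdiff(seq_len(n), pivots)
  if (length(free) == 0) {
    return(matrix(0, nrow = n, ncol = 0))
  }
  out <- matrix(0, nrow = n, ncol = length(free))
  for (k in seq_along(free)) {
    j <- free[k]
    xn <- numeric(n)
    xd <- rep(1, n)
    xn[j] <- 1
    for (ri in seq_along(pivots)) {
      pc <- pivots[ri]
      # x_pc = -(entry at row ri, column j)
      xn[pc] <- -rr$N[ri, j]
      xd[pc] <- rr$D[ri, j]
    }
    l <- lcm_all(xd)
    v <- xn * (l / xd)
    check_exact(v)
    out[, k] <- int_reduce(v)
  }
  out
}
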