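# Exact rational arithmetic on small integer problems.
#
# Numerators and denominators are stored as doubles but kept integral and
# reduced after every operation, so all values are exact as long as they stay
# below 2^53 -- far beyond anything a chemical balancing problem produces.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

.gcd_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(1)
  Reduce(.gcd2, x)
}

.lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / .gcd2(a, b) * b)
}

.rat_reduce <- function(n, d) {
  stopifnot(all(d != 0))
  s <- ifelse(d < 0, -1, 1)
  n <- n * s
  d <- d * s
  g <- mapply(function(ni, di) if (ni == 0) di else .gcd2(ni, di), n, d)
  list(n = n / g, d = d / g)
}

.rat_sub <- function(n1, d1, n2, d2) {
  .rat_reduce(n1 * d2 - n2 * d1, d1 * d2)
}

.rat_mul <- function(n1, d1, n2, d2) {
  .rat_reduce(n1 * n2, d1 * d2)
}

# Exact rational nullspace of an integer matrix A (rows = constraints,
# cols = unknowns) via Gauss-Jordan elimination. Returns a list of basis
# vectors, each a rational vector list(n =, d =).
.rat_nullspace <- function(A) {
  m <- nrow(A); p <- ncol(A)
  N <- A
  D <- matrix(1, m, p)
  pivot_col <- integer(0)
  row <- 1L
  for (col in seq_len(p)) {
    if (row > m) break
    pr <- which(N[row:m, col] != 0)
    if (length(pr) == 0L) next
    pr <- pr[1L] + row - 1L
    if (pr != row) {
      N[c(pr, row), ] <- N[c(row, pr), ]
      D[c(pr, row), ] <- D[c(row, pr), ]
    }
    # scale pivot row to make the pivot 1
    pn <- N[row, col]; pd <- D[row, col]
    for (j in seq_len(p)) {
      r <- .rat_mul(N[row, j], D[row, j], pd, pn)
      N[row, j] <- r$n; D[row, j] <- r$d
    }
    # eliminate this column from every other row
    for (i in seq_len(m)) {
      if (i == row || N[i, col] == 0) next
      fn <- N[i, col]; fd <- D[i, col]
      for (j in seq_len(p)) {
        prod <- .rat_mul(fn, fd, N[row, j], D[row, j])
        r <- .rat_sub(N[i, j], D[i, j], prod$n, prod$d)
        N[i, j] <- r$n; D[i, j] <- r$d
      }
    }
    pivot_col <- c(pivot_col, col)
    row <- row + 1L
  }
  free_cols <- setdiff(seq_len(p), pivot_col)
  basis <- list()
  for (fc in free_cols) {
    vn <- numeric(p); vd <- rep(1, p)
    vn[fc] <- 1
    for (k in seq_along(pivot_col)) {
      # pivot row k gives x[pivot_col[k]] = -sum over free cols of coeff * x[free]
      r <- .rat_reduce(-N[k, fc], D[k, fc])
      vn[pivot_col[k]] <- r$n
      vd[pivot_col[k]] <- r$d
    }
    basis[[length(basis) + 1L]] <- list(n = vn, d = vd)
  }
  basis
}

# Scale a rational vector to the smallest integer vector with the same
# direction and positive entries; error when signs are mixed.
.rat_to_min_integers <- function(v) {
  l <- Reduce(.lcm2, v$d)
  x <- v$n * (l / v$d)
  g <- .gcd_vec(x)
  x <- x / g
  if (any(x == 0) || (any(x > 0) && any(x < 0))) {
    stop("conservation system has no strictly positive solution")
  }
  if (all(x < 0)) x <- -x
  x
}
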