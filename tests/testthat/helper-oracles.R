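# Independent oracles, built from first principles (explicit loops and
# explicit matrix inverses) so they share no code path with the package
# internals they check.

# Treatment layout, design matrix and covariance written out literally.
oracle_layout <- function(J) {
  m <- matrix(0, J, J + 1)
  for (j in 1:J) for (t in 1:(J + 1)) if (t >= j + 1) m[j, t] <- 1
  m
}

oracle_X <- function(j, J) {
  T <- J + 1
  X <- matrix(0, T, T + 1)
  X[, 1] <- 1
  for (t in 2:T) X[t, t] <- 1          # dummy for period t sits in column t
  X[, T + 1] <- oracle_layout(J)[j, ]
  X
}

oracle_V <- function(T, rho, sigma2 = 1) {
  V <- matrix(0, T, T)
  for (a in 1:T) for (b in 1:T) V[a, b] <- sigma2 * rho^abs(a - b)
  V
}

oracle_weights <- function(T, r) {
  w <- numeric(T)
  for (t in 1:T) w[t] <- (1 - r)^(t - 1) - (1 - r)^t
  w[T] <- (1 - r)^(T - 1)
  w
}

# Literal accumulation of the double sum  sum_j sum_t n_jt X_jt' V_t^-1 X_jt
# with explicit inverses at each truncation, then explicit inversion; returns
# the treatment-variance entry for total sample size 1.
oracle_variance <- function(p, J, rho, r, sigma2 = 1) {
  T <- J + 1
  V <- oracle_V(T, rho, sigma2)
  w <- oracle_weights(T, r)
  M <- matrix(0, T + 1, T + 1)
  for (j in 1:J) {
    X <- oracle_X(j, J)
    for (t in 1:T) {
      Xt <- X[1:t, , drop = FALSE]
      Vt_inv <- solve(V[1:t, 1:t, drop = FALSE])
      M <- M + p[j] * w[t] * t(Xt) %*% Vt_inv %*% Xt
    }
  }
  solve(M)[T + 1, T + 1]
}

oracle_information <- function(j, J, rho, r, sigma2 = 1) {
  T <- J + 1
  V <- oracle_V(T, rho, sigma2)
  w <- oracle_weights(T, r)
  A <- matrix(0, T + 1, T + 1)
  X <- oracle_X(j, J)
  for (t in 1:T) {
    Xt <- X[1:t, , drop = FALSE]
    A <- A + w[t] * t(Xt) %*% solve(V[1:t, 1:t, drop = FALSE]) %*% Xt
  }
  A
}

# Textbook GLS on stacked complete data (no dropout): whiten each
# individual's block with the inverse Cholesky factor and run ordinary least
# squares via the normal equations.
oracle_gls_complete <- function(data, J, rho, sigma2) {
  T <- J + 1
  V <- oracle_V(T, rho, sigma2)
  Linv <- solve(t(chol(V)))            # V = L L', whitening by L^-1
  Xs <- NULL
  ys <- NULL
  for (id in unique(data$individual_id)) {
    di <- data[data$individual_id == id, ]
    di <- di[order(di$period), ]
    X <- oracle_X(di$sequence[1], J)
    Xs <- rbind(Xs, Linv %*% X)
    ys <- c(ys, Linv %*% di$outcome)
  }
  solve(t(Xs) %*% Xs, t(Xs) %*% ys)[, 1]
}
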