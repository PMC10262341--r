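#' Per-individual information matrix of one sequence
#'
#' Computes the expected Fisher information contributed by a single
#' individual in sequence `j`, averaged over the dropout distribution:
#' \deqn{A_j = \sum_{t=1}^{T} w_t \, X_{jt}' V_t^{-1} X_{jt},}
#' where `X_jt` and `V_t` are the design matrix and residual covariance
#' truncated to the first `t` periods and `w_t` are the attrition weights
#' (the probability that the individual's last observation falls at the end
#' of period `t`). Without attrition (`r = 0`) this reduces to
#' `X_j' V^{-1} X_j`.
#'
#' @param j Sequence index in `1:J`.
#' @param design An [sw_design()] object.
#' @return A symmetric positive semidefinite `(T + 1) x (T + 1)` matrix,
#'   in units of inverse squared outcome units per individual.
#' @export
sequence_information <- function(j, design) {
  design <- as_sw_design(design)
  X <- design_matrix(j, design)
  V <- exp_decay_covariance(design)
  w <- attrition_weights(design)
  T <- design$T
  A <- matrix(0, T + 1L, T + 1L, dimnames = list(colnames(X), colnames(X)))
  for (t in seq_len(T)) {
    if (w[t] == 0) next
    Xt <- X[seq_len(t), , drop = FALSE]
    Vt <- V[seq_len(t), seq_len(t), drop = FALSE]
    A <- A + w[t] * crossprod(Xt, solve(Vt, Xt))
  }
  A
}

#' All per-sequence information matrices
#'
#' Convenience wrapper returning `sequence_information(j, design)` for every
#' sequence; precompute once when evaluating many allocations of the same
#' design.
#'
#' @param design An [sw_design()] object.
#' @return A list of `J` matrices, each `(T + 1) x (T + 1)`.
#' @export
information_matrices <- function(design) {
  design <- as_sw_design(design)
  lapply(seq_len(design$J), sequence_information, design = design)
}

check_proportions <- function(p, J, tol = 1e-8) {
  if (!is.numeric(p) || length(p) != J || anyNA(p))
    stop("allocation `p` must be a numeric vector of length J = ", J,
         call. = FALSE)
  if (any(p < 0) || any(p > 1))
    stop("allocation proportions must lie in [0, 1].", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop("allocation proportions must sum to 1 (got ", format(sum(p)), ").",
         call. = FALSE)
  invisible(p)
}

check_bounds <- function(lower, upper, J) {
  if (is.null(lower)) lower <- rep(0, J)
  if (is.null(upper)) upper <- rep(1, J)
  if (length(lower) == 1L) lower <- rep(lower, J)
  if (length(upper) == 1L) upper <- rep(upper, J)
  if (length(lower) != J || length(upper) != J ||
      anyNA(lower) || anyNA(upper))
    stop("bounds must be scalars or length-J vectors without NAs.", call. = FALSE)
  if (any(lower < 0) || any(upper > 1) || any(lower > upper))
    stop("bounds must satisfy 0 <= lower <= upper <= 1 per sequence.",
         call. = FALSE)
  if (sum(lower) > 1 + 1e-12 || sum(upper) < 1 - 1e-12)
    stop("infeasible bounds: need sum(lower) <= 1 <= sum(upper) so the ",
         "proportions can sum to 1.", call. = FALSE, domain = NA)
  list(lower = lower, upper = upper)
}

# Total information for allocation p given precomputed per-sequence matrices.
total_information <- function(p, A) {
  M <- A[[1L]] * p[1L]
  for (j in seq_along(A)[-1L]) M <- M + A[[j]] * p[j]
  M
}

variance_from_information <- function(M) {
  d <- nrow(M)
  rc <- rcond(M)
  if (rc < .Machine$double.eps)
    stop("singular total information matrix: the treatment effect is not ",
         "estimable under this allocation.", call. = FALSE)
  if (rc < 1e-12)
    warning("total information matrix is ill-conditioned (rcond = ",
            format(rc, digits = 3), "); variance may be inaccurate.",
            call. = FALSE)
  v <- solve(M)[d, d]
  if (!is.finite(v) || v <= 0)
    stop("non-positive treatment variance from information inversion; ",
         "the design/allocation is degenerate.", call. = FALSE)
  v
}

#' Variance of the GLS treatment-effect estimator
#'
#' For an allocation `p` of individuals over the `J` sequences, the
#' generalized least squares estimator of the sustained treatment effect
#' has variance
#' \deqn{\mathrm{var}(\hat\gamma) = \left[\Big(\sum_j n p_j A_j\Big)^{-1}\right]_{T+1,\,T+1},}
#' the diagonal entry of the inverted total information corresponding to the
#' treatment parameter (the last coefficient). With `n_total = 1` (the
#' default) the variance is reported per unit total sample size; the
#' variance at sample size `n` is this value divided by `n`, and the
#' variance-minimizing allocation does not depend on `n`.
#'
#' @param p Numeric length-`J` vector of proportions on the simplex.
#' @param design An [sw_design()] object.
#' @param n_total Total sample size; defaults to 1 (per-unit variance).
#' @param A Optional precomputed list from [information_matrices()] (for
#'   repeated evaluation).
#' @return A positive scalar, `var(gamma_hat)`.
#' @examples
#' d <- sw_design(J = 4, rho = 0.4)
#' treatment_variance(uniform_allocation(4), d)
#' @export
treatment_variance <- function(p, design, n_total = 1, A = NULL) {
  design <- as_sw_design(design)
  check_proportions(p, design$J)
  if (length(n_total) != 1L || !is.numeric(n_total) || n_total <= 0)
    stop("`n_total` must be a positive scalar.", call. = FALSE)
  if (is.null(A)) A <- information_matrices(design)
  variance_from_information(total_information(p, A)) / n_total
}
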