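#' Exponential-decay residual covariance matrix
#'
#' Builds the `T x T` covariance matrix of an individual's residual vector
#' under the exponential-decay (first-order autoregressive) correlation
#' structure: entry `(t, t')` equals `sigma2 * rho^|t - t'|`. The
#' correlation between two measurements shrinks geometrically with their
#' time lag, which is more realistic for repeated measurements on the same
#' person than compound symmetry.
#'
#' The matrix is symmetric Toeplitz and positive definite for any
#' `rho` in `[0, 1)`.
#'
#' @param design An [sw_design()] object supplying `T`, `rho`, `sigma2`.
#' @return A `T x T` numeric matrix.
#' @examples
#' exp_decay_covariance(sw_design(J = 2, rho = 0.5))
#' @export
exp_decay_covariance <- function(design) {
  design <- as_sw_design(design)
  T <- design$T
  idx <- seq_len(T)
  design$sigma2 * design$rho^abs(outer(idx, idx, `-`))
}

#' Leading principal submatrix of a residual covariance
#'
#' Keeps the first `t` rows and columns of the covariance matrix,
#' corresponding to an individual observed only through period `t`. A
#' leading principal submatrix of a positive definite matrix is itself
#' positive definite.
#'
#' @param V Covariance matrix from [exp_decay_covariance()].
#' @param t Last observed period, in `1:nrow(V)`.
#' @return The `t x t` leading principal submatrix of `V`.
#' @export
truncate_covariance <- function(V, t) {
  if (length(t) != 1L || !is.numeric(t) || is.na(t) || t != round(t) ||
      t < 1 || t > nrow(V))
    stop("truncation period `t` must be an integer in 1..", nrow(V), call. = FALSE)
  V[seq_len(t), seq_len(t), drop = FALSE]
}

#' Distribution of last-observation times under constant attrition
#'
#' With a constant probability `r` of dropping out between any two adjacent
#' periods, the expected fraction of individuals whose last observation is
#' at the end of period `t` is `(1 - r)^(t - 1) - (1 - r)^t` for
#' `t < T`. Individuals still present at the final period are completers,
#' so the final weight is the survival mass `(1 - r)^(T - 1)`; the weights
#' then form a proper probability distribution (they sum to one and total
#' sample size is conserved). Everyone contributes at least the period-1
#' measurement: dropout before the first measurement is not modeled.
#'
#' @param design An [sw_design()] object supplying `T` and `r`.
#' @return A length-`T` numeric vector of nonnegative weights summing to 1.
#'   For `r = 0` this is `(0, ..., 0, 1)`: everyone completes.
#' @examples
#' attrition_weights(sw_design(J = 2, rho = 0.3, r = 0.2))  # (0.2, 0.16, 0.64)
#' @export
attrition_weights <- function(design) {
  design <- as_sw_design(design)
  T <- design$T
  s <- (1 - design$r)^(0:T)           # survival through each period boundary
  w <- s[seq_len(T)] - s[seq_len(T) + 1L]
  w[T] <- s[T]                        # completers: still observed at period T
  names(w) <- paste0("period_", seq_len(T))
  w
}
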