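#' Specify an individually randomized stepped-wedge design
#'
#' Bundles the parameters that define one design problem: the number of
#' treatment sequences `J` (so the trial has `T = J + 1` measurement
#' periods), the within-person correlation `rho` between measurements one
#' period apart, the per-period attrition rate `r`, and the residual
#' variance `sigma2`.
#'
#' All individuals start in the control condition; at the beginning of each
#' period one sequence crosses over to the intervention, so that sequence
#' `j` receives the intervention from period `j + 1` onward and every
#' sequence ends on the intervention. A measurement is taken at the end of
#' each period. Residuals within an individual follow an exponential-decay
#' (first-order autoregressive) correlation structure
#' `cor = rho^|t - t'|`, and an individual still present at period `t`
#' drops out before period `t + 1` with probability `r`.
#'
#' @param J Integer number of treatment sequences, at least 2.
#' @param rho Within-person correlation between adjacent periods, in
#'   `[0, 1)`. `rho = 0` gives independent measurements.
#' @param r Per-period attrition rate, in `[0, 1)`. `r = 0` means no
#'   dropout.
#' @param sigma2 Residual variance (squared outcome units), positive.
#'   `sigma2` rescales `var(gamma_hat)` but does not change the optimal
#'   allocation or relative efficiencies.
#' @return An object of class `sw_design`: a list with elements `J`, `T`,
#'   `rho`, `r`, `sigma2`.
#' @examples
#' d <- sw_design(J = 4, rho = 0.4)
#' d$T   # 5 periods
#' @export
sw_design <- function(J, rho, r = 0, sigma2 = 1) {
  if (length(J) != 1L || !is.numeric(J) || is.na(J) || J != round(J) || J < 2)
    stop("`J` must be a single integer >= 2: a stepped-wedge design needs ",
         "at least two sequences to provide a between-sequence contrast.",
         call. = FALSE)
  if (length(rho) != 1L || !is.numeric(rho) || is.na(rho) || rho < 0 || rho >= 1)
    stop("`rho` must lie in [0, 1); rho = 1 makes the residual covariance singular.",
         call. = FALSE)
  if (length(r) != 1L || !is.numeric(r) || is.na(r) || r < 0 || r >= 1)
    stop("`r` must be an attrition probability in [0, 1).", call. = FALSE)
  if (length(sigma2) != 1L || !is.numeric(sigma2) || is.na(sigma2) || sigma2 <= 0)
    stop("`sigma2` must be a positive residual variance.", call. = FALSE)
  structure(
    list(J = as.integer(J), T = as.integer(J) + 1L,
         rho = as.numeric(rho), r = as.numeric(r), sigma2 = as.numeric(sigma2)),
    class = "sw_design"
  )
}

#' @export
print.sw_design <- function(x, ...) {
  cat("Individually randomized stepped-wedge design\n")
  cat(sprintf("  sequences J = %d, periods T = %d\n", x$J, x$T))
  cat(sprintf("  correlation rho = %g, attrition rate r = %g, sigma^2 = %g\n",
              x$rho, x$r, x$sigma2))
  invisible(x)
}

as_sw_design <- function(design) {
  if (!inherits(design, "sw_design"))
    stop("expected an `sw_design` object; see ?sw_design.", call. = FALSE)
  design
}

#' Treatment-indicator layout of a stepped-wedge design
#'
#' Builds the `J x T` binary matrix of treatment indicators, with
#' `T = J + 1` periods: entry `(j, t)` is 1 when sequence `j` is on the
#' intervention in period `t`, i.e. when `t >= j + 1`. All sequences start
#' in control (first column all zero) and end on intervention (last column
#' all one), with one sequence crossing over at the start of each period.
#'
#' @param J Integer number of sequences, at least 2.
#' @return A `J x (J + 1)` 0/1 matrix with informative dimnames.
#' @examples
#' sequence_layout(3)
#' @export
sequence_layout <- function(J) {
  if (length(J) != 1L || !is.numeric(J) || is.na(J) || J != round(J) || J < 2)
    stop("`J` must be a single integer >= 2.", call. = FALSE)
  J <- as.integer(J)
  T <- J + 1L
  m <- outer(seq_len(J), seq_len(T), function(j, t) as.numeric(t >= j + 1L))
  dimnames(m) <- list(paste0("sequence_", seq_len(J)), paste0("period_", seq_len(T)))
  m
}

#' Write a sequence layout to CSV
#'
#' Exports the treatment-indicator matrix (rows = sequences, columns =
#' periods, values 0/1) as a plain CSV file.
#'
#' @param layout Matrix from [sequence_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = TRUE)
  invisible(path)
}

#' Fixed-effects design matrix of one sequence
#'
#' Assembles the `T x (T + 1)` fixed-effects matrix for an individual in
#' sequence `j`: an intercept column, `T - 1` period dummies for periods
#' `2, ..., T` (period 1 is the reference, fixing its period effect at zero
#' for identifiability), and the treatment-indicator column for sequence
#' `j`. The coefficient vector it multiplies is
#' `(beta, tau_2, ..., tau_T, gamma)`, with the treatment effect `gamma`
#' last.
#'
#' @param j Sequence index in `1:J`.
#' @param design An [sw_design()] object.
#' @return A `T x (T + 1)` numeric matrix with column names
#'   `(Intercept)`, `period_2`, ..., `period_T`, `treatment`.
#' @examples
#' design_matrix(1, sw_design(J = 2, rho = 0.3))
#' @export
design_matrix <- function(j, design) {
  design <- as_sw_design(design)
  if (length(j) != 1L || !is.numeric(j) || is.na(j) || j != round(j) ||
      j < 1 || j > design$J)
    stop("sequence index `j` must be an integer in 1..J = 1..", design$J,
         call. = FALSE)
  T <- design$T
  X <- cbind(1, rbind(rep(0, T - 1L), diag(T - 1L)),
             sequence_layout(design$J)[j, ])
  dimnames(X) <- list(paste0("period_", seq_len(T)),
                      c("(Intercept)", paste0("period_", 2:T), "treatment"))
  X
}

#' Truncate a design matrix to an individual's observed periods
#'
#' Keeps the first `t` rows of a fixed-effects matrix, corresponding to an
#' individual whose last observation is at the end of period `t` (monotone
#' dropout). All `T + 1` columns are retained.
#'
#' @param X A design matrix from [design_matrix()].
#' @param t Last observed period, in `1:nrow(X)`.
#' @return The first `t` rows of `X`.
#' @export
truncate_design <- function(X, t) {
  if (length(t) != 1L || !is.numeric(t) || is.na(t) || t != round(t) ||
      t < 1 || t > nrow(X))
    stop("truncation period `t` must be an integer in 1..", nrow(X), call. = FALSE)
  X[seq_len(t), , drop = FALSE]
}
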