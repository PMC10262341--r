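#' Uniform allocation
#'
#' The conventional default allocation assigning an equal proportion `1/J`
#' of individuals to every treatment sequence.
#'
#' @param J Integer number of sequences, at least 2.
#' @return A numeric length-`J` vector of equal proportions.
#' @export
uniform_allocation <- function(J) {
  if (length(J) != 1L || !is.numeric(J) || is.na(J) || J != round(J) || J < 2)
    stop("`J` must be a single integer >= 2.", call. = FALSE)
  rep(1 / J, as.integer(J))
}

#' Relative efficiency of an allocation against the optimal one
#'
#' Quantifies the precision lost by using allocation `p` instead of the
#' variance-minimizing allocation:
#' `RE = var(gamma_hat; p*) / var(gamma_hat; p)`, a number in `(0, 1]`
#' that equals 1 when `p` is itself optimal. A relative efficiency of
#' `RE` means the comparison allocation needs its total sample size
#' inflated by a factor `1 / RE` to match the optimal allocation's
#' precision.
#'
#' @param p Numeric length-`J` allocation to evaluate (e.g.
#'   [uniform_allocation()]).
#' @param design An [sw_design()] object.
#' @param optimal Optional precomputed [optimize_allocation()] result for
#'   this design (avoids re-optimizing).
#' @param ... Passed to [optimize_allocation()] when `optimal` is missing.
#' @return The relative efficiency, a scalar in `(0, 1]`.
#' @examples
#' d <- sw_design(J = 4, rho = 0.4)
#' relative_efficiency(uniform_allocation(4), d)
#' @export
relative_efficiency <- function(p, design, optimal = NULL, ...) {
  design <- as_sw_design(design)
  if (is.null(optimal)) optimal <- optimize_allocation(design, ...)
  stopifnot(inherits(optimal, "sw_opt"))
  optimal$variance / treatment_variance(p, design)
}

#' Sample-size inflation implied by a relative efficiency
#'
#' Converts a relative efficiency into the percent increase in total sample
#' size the less efficient allocation needs to match the optimal
#' allocation's precision: `(1 / RE - 1) * 100`. A relative efficiency of
#' 0.8 corresponds to a 25% larger sample.
#'
#' @param RE Relative efficiency in `(0, 1]`.
#' @return Percent inflation, a nonnegative scalar.
#' @examples
#' sample_size_inflation(0.8)  # 25
#' @export
sample_size_inflation <- function(RE) {
  if (!is.numeric(RE) || anyNA(RE) || any(RE <= 0) || any(RE > 1))
    stop("`RE` must lie in (0, 1].", call. = FALSE)
  (1 / RE - 1) * 100
}

#' Efficiency of the uniform allocation over a parameter grid
#'
#' For every combination of sequence count, correlation and attrition rate,
#' finds the optimal allocation and compares the uniform allocation to it.
#' This is the tabular counterpart of plotting relative-efficiency curves
#' against `rho` for several designs.
#'
#' @param J_values Integer vector of sequence counts (default `3:6`).
#' @param rho_values Correlations (default `seq(0.1, 0.9, by = 0.1)`).
#' @param r_values Attrition rates (default `c(0, 0.05, 0.2)`).
#' @param lower,upper Optional allocation bounds applied to every cell.
#' @param sigma2 Residual variance (a pure scale factor; default 1).
#' @param n_starts,seed Passed to [optimize_allocation()] for every cell.
#' @return A data frame with one row per `(J, rho, r)` cell and columns
#'   `J`, `rho`, `r`, `p_1 ... p_Jmax` (optimal proportions, `NA`-padded
#'   when `J < Jmax`), `var_star`, `var_uniform`, `relative_efficiency`,
#'   `inflation_percent`. Cells whose optimization fails are kept as `NA`
#'   rows rather than aborting the grid; failed cells are listed in the
#'   `failures` attribute.
#' @examples
#' efficiency_grid(J_values = 3, rho_values = c(0.2, 0.8), r_values = 0)
#' @export
efficiency_grid <- function(J_values = 3:6,
                            rho_values = seq(0.1, 0.9, by = 0.1),
                            r_values = c(0, 0.05, 0.2),
                            lower = NULL, upper = NULL, sigma2 = 1,
                            n_starts = 10, seed = 2023) {
  if (length(J_values) == 0 || length(rho_values) == 0 || length(r_values) == 0)
    stop("all grid ranges must be non-empty.", call. = FALSE)
  cells <- expand.grid(r = r_values, rho = rho_values, J = J_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("J", "rho", "r")]
  Jmax <- max(J_values)
  pcols <- paste0("p_", seq_len(Jmax))
  out <- cells
  out[pcols] <- NA_real_
  out$var_star <- NA_real_
  out$var_uniform <- NA_real_
  out$relative_efficiency <- NA_real_
  out$inflation_percent <- NA_real_
  failures <- character(0)

  for (i in seq_len(nrow(cells))) {
    res <- tryCatch({
      d <- sw_design(cells$J[i], cells$rho[i], cells$r[i], sigma2)
      opt <- optimize_allocation(d, lower = lower, upper = upper,
                                 n_starts = n_starts, seed = seed)
      vu <- treatment_variance(uniform_allocation(d$J), d)
      list(p = opt$p_star, vs = opt$variance, vu = vu)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("J=%d rho=%g r=%g: %s", cells$J[i],
                                      cells$rho[i], cells$r[i],
                                      conditionMessage(res)))
      next
    }
    out[i, pcols[seq_along(res$p)]] <- res$p
    out$var_star[i] <- res$vs
    out$var_uniform[i] <- res$vu
    re <- res$vs / res$vu
    out$relative_efficiency[i] <- re
    out$inflation_percent[i] <- (1 / re - 1) * 100
  }
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
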