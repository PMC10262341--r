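# Monte Carlo validation of the analytic variance: simulate trial data under
# the outcome model Y = beta + tau_t + x_jt * gamma + eps with exponential-
# decay residual correlation and monotone MCAR dropout, fit the GLS
# estimator with known V, and compare the empirical variance of gamma_hat
# with the analytic one.

#' Largest-remainder apportionment of a total into integer counts
#'
#' Rounds `p * n_total` to integers that sum exactly to `n_total`: each
#' sequence gets the floor of its exact share, and the remaining units go
#' to the sequences with the largest fractional remainders (ties broken by
#' lower index). Deterministic; uses no random numbers.
#'
#' @param p Proportions summing to 1.
#' @param n_total Positive integer total.
#' @return Integer vector of counts summing to `n_total`.
#' @export
apportion <- function(p, n_total) {
  if (length(n_total) != 1L || n_total < 1 || n_total != round(n_total))
    stop("`n_total` must be a positive integer.", call. = FALSE)
  exact <- p * n_total
  n <- floor(exact)
  left <- round(n_total - sum(n))
  if (left > 0) {
    frac <- exact - n
    take <- order(-frac, seq_along(p))[seq_len(left)]
    n[take] <- n[take] + 1
  }
  as.integer(n)
}

#' Simulate an individually randomized stepped-wedge trial
#'
#' Generates long-format outcome data under the linear model
#' `Y_ijt = beta + tau_t + x_jt * gamma + eps_ijt`, where residual vectors
#' are multivariate normal with the exponential-decay covariance of the
#' design, and each individual's last observed period is drawn from the
#' attrition-weight distribution independently of the outcomes (dropout is
#' missing completely at random and monotone: once gone, gone). Every
#' individual is observed at period 1.
#'
#' @param design An [sw_design()] object.
#' @param p Allocation proportions over sequences; converted to integer
#'   headcounts by largest-remainder [apportion()]ment.
#' @param n_total Total number of individuals, at least `J`.
#' @param beta Baseline score (default 0).
#' @param tau Period effects for periods `2, ..., T` (period 1 is the
#'   reference, effect 0); default all zero.
#' @param gamma Sustained treatment effect (default 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame of class `sw_trial` with one row per individual and
#'   period: columns `individual_id`, `sequence`, `period`, `treatment`,
#'   `outcome` (`NA` after dropout), `observed` (logical). The generating
#'   parameters are stored in the `params` attribute.
#' @examples
#' dat <- simulate_trial(sw_design(3, rho = 0.5, r = 0.2),
#'                       uniform_allocation(3), 30, gamma = 1, seed = 1)
#' head(dat)
#' @export
simulate_trial <- function(design, p, n_total, beta = 0, tau = NULL,
                           gamma = 0, seed = NULL) {
  design <- as_sw_design(design)
  J <- design$J; T <- design$T
  check_proportions(p, J)
  if (n_total < J)
    stop("`n_total` must be at least J so each sequence can be represented.",
         call. = FALSE)
  if (is.null(tau)) tau <- rep(0, T - 1L)
  if (length(tau) != T - 1L)
    stop("`tau` must have length T - 1 = ", T - 1L,
         " (period effects for periods 2..T).", call. = FALSE)

  n_j <- apportion(p, n_total)
  if (any(n_j == 0))
    warning("degenerate design: some sequences received zero individuals.",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  V <- exp_decay_covariance(design)
  w <- attrition_weights(design)
  layout <- sequence_layout(J)
  tau_full <- c(0, tau)

  pieces <- vector("list", J)
  id0 <- 0L
  for (j in seq_len(J)) {
    if (n_j[j] == 0L) next
    mu <- beta + tau_full + layout[j, ] * gamma
    E <- MASS::mvrnorm(n_j[j], mu = rep(0, T), Sigma = V)
    if (is.null(dim(E))) E <- matrix(E, nrow = 1L)
    Y <- sweep(E, 2L, mu, `+`)
    t_last <- sample.int(T, n_j[j], replace = TRUE, prob = w)
    obs <- outer(t_last, seq_len(T), `>=`)
    Y[!obs] <- NA_real_
    pieces[[j]] <- data.frame(
      individual_id = rep(id0 + seq_len(n_j[j]), each = T),
      sequence = j,
      period = rep(seq_len(T), times = n_j[j]),
      treatment = rep(layout[j, ], times = n_j[j]),
      outcome = as.numeric(t(Y)),
      observed = as.logical(t(obs))
    )
    id0 <- id0 + n_j[j]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "params") <- list(beta = beta, tau = tau, gamma = gamma,
                              sigma2 = design$sigma2, rho = design$rho,
                              r = design$r, J = J, T = T, seed = seed)
  class(out) <- c("sw_trial", "data.frame")
  out
}

#' Fit the GLS estimator with known residual covariance
#'
#' Estimates the coefficient vector `(beta, tau_2, ..., tau_T, gamma)` by
#' generalized least squares, treating the residual covariance as known
#' (the design-stage assumption): each individual observed through period
#' `t` contributes `X_jt' V_t^{-1} X_jt` to the information and
#' `X_jt' V_t^{-1} y_i` to the score, using the design matrix and
#' covariance truncated to the first `t` periods.
#'
#' @param data An `sw_trial` data frame (or any long-format data frame with
#'   columns `individual_id`, `sequence`, `period`, `outcome`, `observed`
#'   and a monotone observation pattern).
#' @param design The [sw_design()] object used to generate (or assumed to
#'   govern) the data; supplies the known covariance.
#' @return An object of class `sw_gls`: list with `theta_hat`, `cov_theta`,
#'   `gamma_hat`, `var_gamma`, and the realized per-(sequence, last-period)
#'   counts `n_jt`.
#' @export
fit_gls <- function(data, design) {
  design <- as_sw_design(design)
  J <- design$J; T <- design$T
  need <- c("individual_id", "sequence", "period", "outcome", "observed")
  if (!all(need %in% names(data)))
    stop("`data` must have columns ", paste(need, collapse = ", "), call. = FALSE)

  data <- data[order(data$individual_id, data$period), , drop = FALSE]
  ids <- unique(data$individual_id)
  n <- length(ids)
  yw <- matrix(NA_real_, n, T)
  idx_i <- match(data$individual_id, ids)
  yw[cbind(idx_i, data$period)] <- ifelse(data$observed, data$outcome, NA_real_)
  seq_of <- integer(n)
  seq_of[idx_i] <- data$sequence
  t_last <- apply(!is.na(yw), 1L, function(o) {
    k <- which(o)
    if (length(k) == 0L || !identical(k, seq_len(max(k))))
      stop("non-monotone observation pattern: dropout must be permanent and ",
           "start from period 1.", call. = FALSE)
    max(k)
  })

  V <- exp_decay_covariance(design)
  d <- T + 1L
  M <- matrix(0, d, d)
  b <- numeric(d)
  n_jt <- matrix(0L, J, T, dimnames = list(paste0("sequence_", seq_len(J)),
                                           paste0("period_", seq_len(T))))
  for (j in seq_len(J)) {
    Xj <- design_matrix(j, design)
    for (t in seq_len(T)) {
      rows <- which(seq_of == j & t_last == t)
      if (length(rows) == 0L) next
      n_jt[j, t] <- length(rows)
      Xt <- Xj[seq_len(t), , drop = FALSE]
      Wt <- crossprod(Xt, solve(V[seq_len(t), seq_len(t), drop = FALSE]))
      M <- M + length(rows) * (Wt %*% Xt)
      ysum <- colSums(yw[rows, seq_len(t), drop = FALSE])
      b <- b + drop(Wt %*% ysum)
    }
  }
  if (rcond(M) < 1e-14)
    stop("estimability failure: the realized data do not identify all ",
         "coefficients (rank-deficient information).", call. = FALSE)
  theta <- solve(M, b)
  covm <- solve(M)
  cn <- colnames(design_matrix(1L, design))
  names(theta) <- cn
  dimnames(covm) <- list(cn, cn)
  structure(
    list(theta_hat = theta, cov_theta = covm,
         gamma_hat = theta[d], var_gamma = covm[d, d], n_jt = n_jt),
    class = "sw_gls"
  )
}

#' @export
print.sw_gls <- function(x, ...) {
  cat("GLS fit (known residual covariance)\n")
  print(round(x$theta_hat, 4))
  cat(sprintf("gamma_hat = %.4f (var %.6g)\n", x$gamma_hat, x$var_gamma))
  invisible(x)
}

#' Monte Carlo check of the analytic treatment-effect variance
#'
#' Repeatedly simulates a trial and fits the GLS estimator, then compares
#' the empirical variance of `gamma_hat` across replicates with the
#' analytic value `treatment_variance(p, design) / n_total` (the expected-
#' information variance, using expected rather than realized dropout
#' counts). The standard error of the empirical variance uses the normal-
#' theory approximation `var * sqrt(2 / (n_reps - 1))`.
#'
#' @inheritParams simulate_trial
#' @param n_reps Number of replicates, at least 100.
#' @param seed Integer seed; replicate `k` uses `seed + k`.
#' @return An object of class `sw_mc`: list with `empirical_var`, `se`,
#'   `analytic_var`, `z` (standardized discrepancy), `mean_gamma_hat`,
#'   `gamma` (true value), `n_reps`, `n_total`, and `agree` (TRUE when the
#'   empirical variance is within 3 standard errors of the analytic one).
#' @export
monte_carlo_variance <- function(design, p, n_total, beta = 0, tau = NULL,
                                 gamma = 0, n_reps = 1000, seed = 1) {
  design <- as_sw_design(design)
  if (length(n_reps) != 1L || n_reps < 100 || n_reps != round(n_reps))
    stop("`n_reps` must be an integer >= 100 for a meaningful variance check.",
         call. = FALSE)
  g <- numeric(n_reps)
  for (k in seq_len(n_reps)) {
    dat <- simulate_trial(design, p, n_total, beta = beta, tau = tau,
                          gamma = gamma, seed = seed + k)
    g[k] <- fit_gls(dat, design)$gamma_hat
  }
  emp <- stats::var(g)
  se <- emp * sqrt(2 / (n_reps - 1))
  ana <- treatment_variance(p, design) / n_total
  z <- (emp - ana) / se
  structure(
    list(empirical_var = emp, se = se, analytic_var = ana, z = z,
         mean_gamma_hat = mean(g), gamma = gamma,
         n_reps = n_reps, n_total = n_total, agree = abs(z) <= 3),
    class = "sw_mc"
  )
}

#' @export
print.sw_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo variance check (%d replicates, n = %d)\n",
              x$n_reps, x$n_total))
  cat(sprintf("  empirical var(gamma_hat): %.6g (SE %.3g)\n", x$empirical_var, x$se))
  cat(sprintf("  analytic  var(gamma_hat): %.6g\n", x$analytic_var))
  cat(sprintf("  standardized discrepancy z = %.2f -> %s\n", x$z,
              if (x$agree) "agreement (within 3 SE)" else "DISAGREEMENT"))
  invisible(x)
}

#' Write or read trial data as CSV
#'
#' Round-trips `sw_trial` data through a plain long-format CSV with columns
#' `individual_id`, `sequence`, `period`, `treatment`, `outcome`,
#' `observed` (1/0). Missing outcomes are written as empty fields.
#'
#' @param data An `sw_trial` data frame.
#' @param path File path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns an `sw_trial` data frame.
#' @export
write_trial_csv <- function(data, path) {
  out <- data.frame(individual_id = data$individual_id,
                    sequence = data$sequence, period = data$period,
                    treatment = data$treatment, outcome = data$outcome,
                    observed = as.integer(data$observed))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  out <- utils::read.csv(path, na.strings = "")
  need <- c("individual_id", "sequence", "period", "treatment", "outcome",
            "observed")
  if (!all(need %in% names(out)))
    stop("trial CSV must have header columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out$observed <- as.logical(out$observed)
  class(out) <- c("sw_trial", "data.frame")
  out
}
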