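# Allocation optimization.
#
# The objective p -> [ (sum_j p_j A_j)^{-1} ]_{dd} is a matrix-fractional
# function e' M(p)^{-1} e with M(p) linear in p, hence convex over the
# feasible polytope {p : sum p = 1, lower <= p <= upper}. A log-barrier
# interior method (stats::constrOptim) with the analytic gradient
#   d var / d p_j = -(u' A_j u),  u = M(p)^{-1} e,
# converges to the global minimum; multiple starts guard against numerical
# stalls, and an active-set polish places solutions exactly on their box
# bounds.

# Objective and gradient over the J-1 free coordinates (p_J implied).
# `fixed` marks coordinates clamped at known values during polishing.
make_objective <- function(A, fixed_idx = integer(), fixed_val = numeric()) {
  d <- nrow(A[[1L]])
  J <- length(A)
  free_idx <- setdiff(seq_len(J), fixed_idx)
  m <- length(free_idx)
  Mfixed <- matrix(0, d, d)
  for (k in seq_along(fixed_idx)) Mfixed <- Mfixed + fixed_val[k] * A[[fixed_idx[k]]]
  total <- 1 - sum(fixed_val)
  Afree <- A[free_idx]

  assemble <- function(q) {
    pf <- c(q, total - sum(q))
    M <- Mfixed
    for (k in seq_len(m)) M <- M + pf[k] * Afree[[k]]
    list(p = pf, M = M)
  }
  fn <- function(q) {
    M <- assemble(q)$M
    v <- tryCatch(solve(M)[d, d], error = function(e) NA_real_)
    if (!is.finite(v) || v <= 0) return(.Machine$double.xmax)
    v
  }
  gr <- function(q) {
    M <- assemble(q)$M
    u <- tryCatch(solve(M)[, d], error = function(e) rep(NA_real_, d))
    if (anyNA(u)) return(rep(0, m - 1L))
    gp <- -vapply(Afree, function(a) drop(crossprod(u, a %*% u)), numeric(1))
    gp[seq_len(m - 1L)] - gp[m]
  }
  list(fn = fn, gr = gr, free_idx = free_idx, total = total, m = m)
}

# One barrier solve over free coordinates with box bounds (strict interior
# start required). Returns the full-length p.
solve_interior <- function(A, lower, upper, p_start,
                           fixed_idx = integer(), fixed_val = numeric()) {
  obj <- make_objective(A, fixed_idx, fixed_val)
  m <- obj$m
  fi <- obj$free_idx
  if (m == 0L) {
    p <- numeric(length(A)); p[fixed_idx] <- fixed_val
    return(list(p = p, value = obj$fn(numeric(0)), convergence = 0L))
  }
  if (m == 1L) {
    p <- numeric(length(A)); p[fixed_idx] <- fixed_val; p[fi] <- obj$total
    return(list(p = p, value = obj$fn(numeric(0)), convergence = 0L))
  }
  lo <- lower[fi]; up <- upper[fi]
  q0 <- p_start[fi][seq_len(m - 1L)]
  # linear constraints ui %*% q >= ci:
  #   q_k >= lo_k, -q_k >= -up_k (k < m), and bounds on the implied last
  #   free coordinate: total - sum(q) in [lo_m, up_m].
  I <- diag(m - 1L)
  ui <- rbind(I, -I, rep(-1, m - 1L), rep(1, m - 1L))
  ci <- c(lo[seq_len(m - 1L)], -up[seq_len(m - 1L)],
          lo[m] - obj$total, obj$total - up[m])
  res <- tryCatch(
    stats::constrOptim(q0, f = obj$fn, grad = obj$gr, ui = ui, ci = ci,
                       mu = 1e-05, outer.iterations = 200, outer.eps = 1e-12,
                       control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  p <- numeric(length(A))
  p[fixed_idx] <- fixed_val
  p[fi] <- c(res$par, obj$total - sum(res$par))
  list(p = p, value = res$value, convergence = res$convergence)
}

# Snap near-active box constraints to their bound and re-optimize the free
# coordinates; repeat until the active set is stable.
polish_active_set <- function(A, lower, upper, p, snap_tol = 1e-5) {
  J <- length(A)
  for (pass in seq_len(J)) {
    at_lo <- which(p - lower < snap_tol)
    at_up <- which(upper - p < snap_tol)
    at_up <- setdiff(at_up, at_lo)
    fixed_idx <- c(at_lo, at_up)
    if (length(fixed_idx) == 0L) return(p)
    fixed_val <- c(lower[at_lo], upper[at_up])
    if (1 - sum(fixed_val) < -1e-10) return(p)      # over-snapped; keep as is
    cand <- solve_interior(A, lower, upper, p, fixed_idx, fixed_val)
    if (is.null(cand)) return(p)
    if (identical(sort(fixed_idx),
                  sort(c(which(cand$p - lower < snap_tol),
                         setdiff(which(upper - cand$p < snap_tol),
                                 which(cand$p - lower < snap_tol)))))) {
      return(cand$p)
    }
    p <- cand$p
  }
  p
}

# Strictly interior feasible point: lower + s * (upper - lower) scaled to the
# simplex; used as the uniform-start fallback and as the blending anchor for
# randomized starts.
interior_point <- function(lower, upper) {
  span <- sum(upper - lower)
  if (span <= 0) return(lower)
  lower + (1 - sum(lower)) / span * (upper - lower)
}

random_start <- function(J, lower, upper, anchor) {
  d <- stats::rexp(J)
  d <- d / sum(d)
  if (all(d > lower + 1e-8) && all(d < upper - 1e-8)) return(d)
  # blend toward the interior anchor until strictly inside the box
  dir <- d - anchor
  alpha <- 1
  for (j in seq_len(J)) {
    if (dir[j] > 0) alpha <- min(alpha, (upper[j] - 1e-8 - anchor[j]) / dir[j])
    if (dir[j] < 0) alpha <- min(alpha, (lower[j] + 1e-8 - anchor[j]) / dir[j])
  }
  anchor + max(0, 0.9 * alpha) * dir
}

#' Optimal allocation of individuals to treatment sequences
#'
#' Finds the allocation `p*` over the `J` sequences that minimizes the
#' variance of the GLS treatment-effect estimator ([treatment_variance()]),
#' subject to the simplex constraint `sum(p) = 1` and optional per-sequence
#' box constraints `lower <= p <= upper`. The allocation that maximizes the
#' precision of the treatment effect estimate also maximizes the power of
#' the test on the treatment effect at a given total sample size.
#'
#' The objective is convex over the feasible polytope (a matrix-fractional
#' function of `p`), and is minimized by an interior-point (log-barrier)
#' method with analytic gradients, started from the uniform allocation plus
#' `n_starts` randomized starting vectors to guard against numerical
#' stalls. Solutions within `1e-5` of a box bound are polished onto the
#' bound exactly and the remaining coordinates re-optimized.
#'
#' @param design An [sw_design()] object.
#' @param lower,upper Optional per-sequence allocation bounds; scalars are
#'   recycled to length `J`. Must satisfy
#'   `sum(lower) <= 1 <= sum(upper)`.
#' @param n_starts Number of additional randomized starting vectors beyond
#'   the uniform start. Default 10.
#' @param seed Integer seed making the randomized starts (and hence the
#'   output) reproducible. Default 2023.
#' @return An object of class `sw_opt`: a list with elements
#'   `p_star` (optimal proportions), `variance` (the minimized
#'   `var(gamma_hat)` per unit total sample size, recomputed at `p_star`),
#'   `converged`, `active_bounds` (data frame of sequences sitting on a
#'   bound, within `1e-6`), `starts_used`, `lower`, `upper`, `seed`, and
#'   the `design`.
#' @examples
#' opt <- optimize_allocation(sw_design(J = 4, rho = 0.4))
#' round(opt$p_star, 2)  # 0.33 0.17 0.17 0.33
#' @export
optimize_allocation <- function(design, lower = NULL, upper = NULL,
                                n_starts = 10, seed = 2023) {
  design <- as_sw_design(design)
  J <- design$J
  b <- check_bounds(lower, upper, J)
  lower <- pmax(b$lower, 1e-9)          # strict interior floor of the simplex
  upper <- pmin(b$upper, 1 - 1e-9)
  if (length(n_starts) != 1L || n_starts < 0 || n_starts != round(n_starts))
    stop("`n_starts` must be a nonnegative integer.", call. = FALSE)

  A <- information_matrices(design)

  # degenerate feasible region: a single point
  if (sum(lower) >= 1 - 1e-12 || sum(upper) <= 1 + 1e-12 ||
      all(upper - lower < 1e-12)) {
    p <- if (sum(lower) >= 1 - 1e-12) lower / sum(lower) else upper / sum(upper)
    v <- variance_from_information(total_information(p, A))
    return(new_sw_opt(p, v, TRUE, lower, upper, 0L, seed, design))
  }

  anchor <- interior_point(lower, upper)
  unif <- rep(1 / J, J)
  starts <- list(if (all(unif > lower + 1e-8) && all(unif < upper - 1e-8))
    unif else anchor)
  if (n_starts > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    for (k in seq_len(n_starts))
      starts[[k + 1L]] <- random_start(J, lower, upper, anchor)
  }

  best <- NULL
  n_ok <- 0L
  for (p0 in starts) {
    sol <- solve_interior(A, lower, upper, p0)
    if (is.null(sol) || !is.finite(sol$value)) next
    p <- polish_active_set(A, lower, upper, sol$p)
    p[J] <- 1 - sum(p[-J])              # exact simplex closure
    v <- tryCatch(variance_from_information(total_information(p, A)),
                  error = function(e) Inf)
    if (!is.finite(v)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || v < best$v - 1e-12 ||
        (abs(v - best$v) <= 1e-12 && lex_less(p, best$p))) {
      best <- list(p = p, v = v)
    }
  }
  if (is.null(best))
    stop("optimization failed to converge from any starting vector; ",
         "check the design parameters and bounds.", call. = FALSE)
  new_sw_opt(best$p, best$v, n_ok > 0L, lower, upper, length(starts), seed, design)
}

lex_less <- function(a, b) {
  d <- a - b
  k <- which(abs(d) > 1e-12)
  length(k) > 0 && d[k[1L]] < 0
}

new_sw_opt <- function(p, v, converged, lower, upper, starts_used, seed, design) {
  names(p) <- paste0("sequence_", seq_along(p))
  at_lo <- which(p - lower < 1e-6)
  at_up <- setdiff(which(upper - p < 1e-6), at_lo)
  active <- data.frame(
    sequence = c(at_lo, at_up),
    side = rep(c("lower", "upper"), c(length(at_lo), length(at_up))),
    stringsAsFactors = FALSE
  )
  active <- active[order(active$sequence), , drop = FALSE]
  rownames(active) <- NULL
  structure(
    list(p_star = p, variance = v, converged = converged,
         active_bounds = active, starts_used = starts_used,
         lower = lower, upper = upper, seed = seed, design = design),
    class = "sw_opt"
  )
}

#' @export
print.sw_opt <- function(x, digits = 4, ...) {
  d <- x$design
  cat(sprintf("Optimal allocation (J = %d, rho = %g, r = %g)\n", d$J, d$rho, d$r))
  tab <- data.frame(sequence = seq_along(x$p_star),
                    proportion = round(x$p_star, digits))
  if (nrow(x$active_bounds) > 0) {
    tab$at_bound <- ""
    tab$at_bound[x$active_bounds$sequence] <- x$active_bounds$side
  }
  print(tab, row.names = FALSE)
  cat(sprintf("var(gamma_hat) per unit total n: %s\n",
              format(x$variance, digits = 8)))
  invisible(x)
}

#' Exhaustive lattice search for the optimal allocation
#'
#' Independent brute-force check of [optimize_allocation()]: enumerates
#' every allocation on the integer lattice of step `resolution` on the
#' simplex that satisfies the box constraints, evaluates
#' `var(gamma_hat)` at each, and returns the minimizer. Intended for small
#' `J` (up to about 4) and `resolution >= 0.01`; the number of lattice
#' points grows combinatorially and the search refuses above `max_points`.
#'
#' @inheritParams optimize_allocation
#' @param resolution Lattice step; `1 / resolution` must be an integer.
#' @param max_points Refusal cap on the number of candidate points.
#' @return A list with `p` (best lattice allocation), `variance`, and
#'   `n_evaluated`.
#' @export
grid_oracle <- function(design, lower = NULL, upper = NULL,
                        resolution = 0.01, max_points = 5e5) {
  design <- as_sw_design(design)
  J <- design$J
  k <- round(1 / resolution)
  if (abs(k * resolution - 1) > 1e-9)
    stop("`resolution` must divide 1 into an integer number of steps.",
         call. = FALSE)
  b <- check_bounds(lower, upper, J)
  lo_i <- ceiling(b$lower * k - 1e-9)
  up_i <- floor(b$upper * k + 1e-9)
  if (sum(lo_i) > k || sum(up_i) < k)
    stop("no lattice point satisfies the bounds at this resolution.",
         call. = FALSE)

  A <- information_matrices(design)
  d <- design$T + 1L
  ed <- c(rep(0, d - 1L), 1)
  Astack <- vapply(A, as.numeric, numeric(d * d))   # d^2 x J

  best_v <- Inf
  best_p <- NULL
  n_eval <- 0L
  counts <- integer(J)

  recurse <- function(j, remaining) {
    if (j == J) {
      if (remaining < lo_i[J] || remaining > up_i[J]) return(invisible())
      counts[J] <<- remaining
      n_eval <<- n_eval + 1L
      if (n_eval > max_points)
        stop("lattice size exceeds max_points = ", max_points,
             "; increase the cap or coarsen the resolution.", call. = FALSE)
      p <- counts / k
      M <- matrix(Astack %*% p, d, d)
      v <- tryCatch(solve(M, ed)[d], error = function(e) Inf)
      if (is.finite(v) && v > 0 && v < best_v) {
        best_v <<- v
        best_p <<- p
      }
      return(invisible())
    }
    hi <- min(up_i[j], remaining - sum(lo_i[(j + 1L):J]))
    lo <- max(lo_i[j], remaining - sum(up_i[(j + 1L):J]))
    if (hi < lo) return(invisible())
    for (a in lo:hi) {
      counts[j] <<- a
      recurse(j + 1L, remaining - a)
    }
  }
  recurse(1L, k)
  if (is.null(best_p))
    stop("no feasible lattice allocation yielded a finite variance.",
         call. = FALSE)
  list(p = best_p, variance = best_v, n_evaluated = n_eval)
}
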