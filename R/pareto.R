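#' Sweep enzyme activities and count of RM systems
#'
#' Evaluates the two ecological objectives on a grid of enzyme activities
#' and RM-system counts: the effective growth rate `lambda_e` and the
#' expected population growth until first phage escape
#' `n_s = lambda_e / (rho * v * p_V)`. Reporting uses the dimensionless
#' convention `1 / (rho * v) = 1 min`, so `n_s = lambda_e / p_V`
#' numerically. Grid points with `lambda_e <= 0` cannot sustain growth and
#' carry `n_s = 0`.
#'
#' @param r_grid,m_grid Enzyme-activity grids (min^-1), typically
#'   log-spaced.
#' @param k_list Integer vector of RM-system counts.
#' @param host A [host_params()] object.
#' @param phage A [phage_params()] object.
#' @param c_r,c_m Enzyme-activity costs.
#' @return A data frame of class `pareto_points` with columns `r`, `m`, `k`,
#'   `lambda_e`, `n_s`, `p_V`.
#' @examples
#' fx <- fixture_params("fig_sweep")
#' pts <- sweep_objectives(10^seq(-2, 3, length.out = 12),
#'                         10^seq(-2, 3, length.out = 12),
#'                         k_list = 1:2, host = fx$host, phage = fx$phage,
#'                         c_r = fx$cost, c_m = fx$cost)
#' @export
sweep_objectives <- function(r_grid, m_grid, k_list, host, phage,
                             c_r = 0, c_m = 0) {
  stopifnot(inherits(host, "host_params"), inherits(phage, "phage_params"),
            all(is.finite(r_grid)), all(is.finite(m_grid)))
  grid <- expand.grid(r = r_grid, m = m_grid, k = as.integer(k_list))
  # mu depends on (r, m) only; evaluate once per activity pair
  rm_pairs <- unique(grid[c("r", "m")])
  rm_pairs$mu <- vapply(seq_len(nrow(rm_pairs)), function(i)
    self_restriction_rate(rm_params(rm_pairs$r[i], rm_pairs$m[i]), host),
    numeric(1))
  grid <- merge(grid, rm_pairs, by = c("r", "m"), sort = FALSE)
  grid$lambda_e <- host$lambda -
    grid$k * (grid$mu + c_r * grid$r + c_m * grid$m)
  grid$p_V <- ifelse(grid$r + grid$m == 0, 1,
                     (grid$m / (grid$r + grid$m))^(grid$k * phage$N_V))
  grid$n_s <- ifelse(grid$lambda_e > 0,
                     grid$lambda_e / (phage$rho * phage$v * grid$p_V), 0)
  out <- grid[c("r", "m", "k", "lambda_e", "n_s", "p_V")]
  class(out) <- c("pareto_points", class(out))
  out
}

#' Extract the Pareto front
#'
#' Returns the maximal non-dominated subset of points under simultaneous
#' maximization of `lambda_e` and `n_s`. A point is dominated when another
#' point is at least as good in both objectives (up to a relative tie
#' tolerance) and strictly better in one.
#'
#' @param points A data frame with columns `lambda_e` and `n_s` (e.g. from
#'   [sweep_objectives()]).
#' @param tol Relative tie tolerance for dominance comparisons.
#' @return The non-dominated subset of `points`, sorted by decreasing
#'   `lambda_e`.
#' @export
pareto_front <- function(points, tol = 1e-12) {
  stopifnot(nrow(points) >= 1, all(c("lambda_e", "n_s") %in% names(points)))
  eps_l <- tol * max(abs(points$lambda_e), 1e-300)
  eps_n <- tol * max(abs(points$n_s), 1e-300)
  ord <- order(-points$lambda_e, -points$n_s)
  p <- points[ord, , drop = FALSE]
  # sweep in decreasing lambda_e: a point is on the front iff its n_s
  # strictly exceeds the best n_s seen so far (ties collapse to one point)
  best_ns <- -Inf
  keep <- logical(nrow(p))
  i <- 1L
  n <- nrow(p)
  while (i <= n) {
    # group of effectively equal lambda_e
    j <- i
    while (j < n && p$lambda_e[j + 1L] >= p$lambda_e[i] - eps_l) j <- j + 1L
    grp <- i:j
    top <- grp[which.max(p$n_s[grp])]
    if (p$n_s[top] > best_ns + eps_n) {
      keep[top] <- TRUE
      best_ns <- p$n_s[top]
    }
    i <- j + 1L
  }
  p[keep, , drop = FALSE]
}

# mu as a plain function of (r, m); shared by the constrained optimizer
mu_of <- function(r, m, host) {
  self_restriction_rate(rm_params(r, m), host)
}

#' Optimal enzyme activities at a fixed effective growth rate
#'
#' Finds the activities `(r, m)` that minimize the phage escape probability
#' `p_V = (m / (r + m))^(k * N_V)` subject to spending exactly the
#' growth-reduction budget `lambda - lambda_e_target` on `k` RM systems:
#' `k * (mu(r, m) + c_r * r + c_m * m) = lambda - lambda_e_target`.
#'
#' The search is deterministic and nested: for each total activity
#' `s = r + m`, the split is pinned by solving the scalar budget constraint
#' for `m` by bisection (the self-restriction rate `mu` decreases
#' monotonically in `m` at fixed `s`); the outer problem over `log(s)` is
#' then solved by golden-section search and polished with a local
#' refinement.
#'
#' @param lambda_e_target Target effective growth rate, in `(0, lambda)`.
#' @param k Number of RM systems.
#' @param host A [host_params()] object.
#' @param phage A [phage_params()] object.
#' @param c_r,c_m Enzyme-activity costs (> 0 for a bounded optimum).
#' @param s_range Search range for the total activity `s = r + m`
#'   (min^-1).
#' @return A list with `r_opt`, `m_opt`, `p_V`, `mu`, `cost_term`
#'   (`c_r * r + c_m * m`), `lambda_e`, `n_s` (in `1/(rho v) = 1 min`
#'   units), and `feasible`.
#' @export
optimal_activities <- function(lambda_e_target, k, host, phage,
                               c_r, c_m, s_range = c(1e-2, 1e7)) {
  stopifnot(inherits(host, "host_params"), inherits(phage, "phage_params"),
            lambda_e_target > 0, lambda_e_target < host$lambda)
  budget <- (host$lambda - lambda_e_target) / k

  # residual of the budget constraint at split m (0 < m < s)
  resid <- function(m, s) mu_of(s - m, m, host) + c_r * (s - m) + c_m * m - budget

  split_for <- function(s) {
    lo <- s * 1e-12
    hi <- s * (1 - 1e-12)
    f_hi <- resid(hi, s)
    if (f_hi > 0) return(NA_real_)       # even maximal m overshoots budget
    f_lo <- resid(lo, s)
    if (f_lo < 0) return(NA_real_)       # cannot spend the budget at this s
    stats::uniroot(resid, c(lo, hi), s = s, tol = 1e-13 * s)$root
  }

  objective <- function(log_s) {
    s <- exp(log_s)
    m <- split_for(s)
    if (is.na(m)) return(Inf)
    k * phage$N_V * log(m / s)          # log p_V, monotone surrogate
  }

  # coarse scan to bracket the feasible region and the minimum
  ls_grid <- seq(log(s_range[1]), log(s_range[2]), length.out = 80)
  vals <- vapply(ls_grid, objective, numeric(1))
  if (all(!is.finite(vals)))
    return(list(feasible = FALSE, r_opt = NA_real_, m_opt = NA_real_,
                p_V = NA_real_, mu = NA_real_, cost_term = NA_real_,
                lambda_e = lambda_e_target, n_s = NA_real_))
  i0 <- which.min(vals)
  lo <- ls_grid[max(1, i0 - 2)]
  hi <- ls_grid[min(length(ls_grid), i0 + 2)]
  opt <- stats::optimize(objective, c(lo, hi), tol = 1e-10)
  s <- exp(opt$minimum)
  m <- split_for(s)
  r <- s - m
  p_V <- (m / s)^(k * phage$N_V)
  mu <- mu_of(r, m, host)
  lambda_e <- host$lambda - k * (mu + c_r * r + c_m * m)
  list(feasible = TRUE, r_opt = r, m_opt = m, p_V = p_V, mu = mu,
       cost_term = c_r * r + c_m * m, lambda_e = lambda_e,
       n_s = if (lambda_e > 0) lambda_e / p_V else 0)
}

#' E. coli / EcoRI reference calibration
#'
#' Applies the constrained optimizer at the measured operating point of an
#' E. coli strain carrying the EcoRI system: replication rate
#' `lambda = 0.017` min^-1, `N_S = 599` EcoRI sites on the host genome,
#' `N_V = 5` on the phage, a single RM system, equal costs
#' `c = c_r = c_m`, and a measured total growth-rate reduction (the
#' "budget") of about `1e-3` min^-1, interpreted as
#' `lambda - lambda_e = mu + c (r + m)`. With `c = 3.7e-7`, the optimizer
#' recovers restriction and methylation activities of order `1.2e3` and
#' `1.5e2` min^-1 respectively, with the growth reduction split equally
#' between enzyme cost and self-restriction.
#'
#' @param cost Equal per-activity cost `c = c_r = c_m`.
#' @param budget Growth-rate reduction `lambda - lambda_e` (min^-1), in
#'   `(0, lambda)`.
#' @param host,phage Host and phage parameters; default to the EcoRI
#'   reference setting.
#' @param k Number of RM systems (default 1).
#' @return As [optimal_activities()].
#' @examples
#' \donttest{
#' calibrate_reference(cost = 3.7e-7, budget = 1e-3)
#' }
#' @export
calibrate_reference <- function(cost = 3.7e-7, budget = 1e-3,
                                host = host_params(lambda = 0.017, N_S = 599),
                                phage = phage_params(N_V = 5),
                                k = 1) {
  stopifnot(budget > 0, budget < host$lambda)
  optimal_activities(lambda_e_target = host$lambda - budget, k = k,
                     host = host, phage = phage, c_r = cost, c_m = cost)
}
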