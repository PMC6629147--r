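#' Configuration for the population Gillespie simulation
#'
#' @param seed Integer RNG seed (or `NULL` to continue the session RNG).
#' @param t_max Simulated time (min).
#' @param n_init Initial number of cells.
#' @param initial_state Per-site methylation law of the initial cells, a
#'   length-3 probability vector (unmethylated, hemi, doubly). Defaults to
#'   fully methylated, the natural state of an established host genome.
#' @param pop_cap Maximum tracked population; beyond it the population is
#'   uniformly subsampled to half the cap and the dilution factor is
#'   book-kept so growth-rate estimates stay unbiased.
#' @param burn_in Fraction of `t_max` discarded before estimation (the
#'   methylation configuration needs time to relax to its quasi-stationary
#'   law).
#' @param n_grid Number of recording intervals.
#' @param n_blocks Number of time blocks for block-bootstrap standard errors.
#' @param mode `"analytic-consistent"` (default) treats demethylation as
#'   continuous rate channels exactly as in the analytic generator;
#'   `"mechanistic"` couples demethylation to division (each doubly
#'   methylated site becomes hemi-methylated in both daughters, each
#'   hemi-methylated site is hemi in one daughter and bare in the other).
#'   The mechanistic rule is provided for model-discrepancy exploration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, t_max = 20000, n_init = 200,
                       initial_state = c(0, 0, 1), pop_cap = 2000,
                       burn_in = 0.2, n_grid = 400, n_blocks = 20,
                       mode = c("analytic-consistent", "mechanistic")) {
  mode <- match.arg(mode)
  stopifnot(t_max > 0, n_init >= 1, pop_cap >= n_init,
            burn_in >= 0, burn_in < 1, n_grid >= n_blocks, n_blocks >= 2)
  initial_state <- as_pq(initial_state)
  structure(list(seed = seed, t_max = t_max, n_init = as.integer(n_init),
                 initial_state = initial_state, pop_cap = as.integer(pop_cap),
                 burn_in = burn_in, n_grid = as.integer(n_grid),
                 n_blocks = as.integer(n_blocks), mode = mode),
            class = "sim_config")
}

# enumerate site-configuration types (n_U, n_H, n_D) in the same order as the
# C++ engine
type_table <- function(N_S) {
  out <- do.call(rbind, lapply(0:N_S, function(u)
    cbind(u = u, h = 0:(N_S - u))))
  data.frame(u = out[, 1], h = out[, 2], d = N_S - out[, 1] - out[, 2])
}

#' Gillespie simulation of a growing self-restricting population
#'
#' Exact stochastic simulation of a population of cells whose `N_S`
#' restriction sites undergo methylation, replication-driven demethylation,
#' and lethal cutting, with cell division at rate `lambda`. Cells with
#' identical site configurations are exchangeable, so the engine tracks
#' counts per configuration; this is an exact realization of the agent-level
#' process. The simulation serves as the independent validation oracle for
#' the analytic self-restriction rate, effective growth rate, and
#' quasi-stationary methylation distribution.
#'
#' Estimators (all computed after the burn-in window):
#' `lambda_e_hat` is the least-squares slope of dilution-corrected log
#' population size versus time; `mu_hat` is total deaths divided by total
#' live-cell time; `p_qsd_hat` is the time-averaged fraction of sites in each
#' methylation class among live cells. Standard errors come from a block
#' bootstrap over `n_blocks` contiguous time blocks.
#'
#' @param rm An [rm_params()] object (`k` is ignored here: the simulation
#'   models one RM system).
#' @param host A [host_params()] object.
#' @param config A [sim_config()].
#' @return An object of class `population_trajectory`: list with `estimates`
#'   (`mu_hat`, `lambda_e_hat`, `p_qsd_hat` and standard errors), the
#'   recorded `trajectory` data frame (`time`, dilution-corrected `log_pop`,
#'   cumulative `deaths`, per-interval live-cell time `celltime`, and
#'   site-class fractions `fU`, `fH`, `fD`), and flags (`extinct`, `ok`).
#' @examples
#' \donttest{
#' fx <- fixture_params("reference")
#' sim <- simulate_population(fx$rm, fx$host, sim_config(seed = 1, t_max = 4000))
#' sim$estimates$mu_hat
#' }
#' @export
simulate_population <- function(rm, host, config = sim_config()) {
  stopifnot(inherits(rm, "rm_params"), inherits(host, "host_params"),
            inherits(config, "sim_config"))
  tt <- type_table(host$N_S)
  init <- with_seed(config$seed, {
    # multinomial site assignment per initial cell
    counts <- integer(nrow(tt))
    states <- stats::rmultinom(config$n_init, host$N_S, config$initial_state)
    for (i in seq_len(ncol(states))) {
      j <- which(tt$u == states[1, i] & tt$h == states[2, i])
      counts[j] <- counts[j] + 1L
    }
    raw <- sim_population_cpp(rm$r, rm$m, host$lambda, host$N_S, counts,
                              config$t_max, config$pop_cap, config$n_grid,
                              config$mode == "mechanistic")
    raw
  })

  filled <- raw_filled <- init$filled
  traj <- data.frame(
    time = init$time, log_pop = init$log_pop,
    deaths = cumsum(init$deaths), celltime = init$celltime,
    fU = ifelse(init$celltime > 0, init$site_U_time / (host$N_S * init$celltime), NA),
    fH = ifelse(init$celltime > 0, init$site_H_time / (host$N_S * init$celltime), NA),
    fD = ifelse(init$celltime > 0, init$site_D_time / (host$N_S * init$celltime), NA)
  )

  start <- max(1L, ceiling(config$burn_in * config$n_grid) + 1L)
  ok <- !init$extinct && filled >= config$n_grid && start < filled
  if (!ok) {
    return(structure(list(
      estimates = list(mu_hat = NA_real_, mu_se = NA_real_,
                       lambda_e_hat = NA_real_, lambda_e_se = NA_real_,
                       p_qsd_hat = rep(NA_real_, 3), p_qsd_se = rep(NA_real_, 3)),
      trajectory = traj, extinct = init$extinct, ok = FALSE,
      config = config), class = "population_trajectory"))
  }

  idx <- start:config$n_grid
  deaths <- init$deaths[idx]
  celltime <- init$celltime[idx]
  siteU <- init$site_U_time[idx]
  siteH <- init$site_H_time[idx]
  siteD <- init$site_D_time[idx]
  tgrid <- init$time[idx]
  lp <- init$log_pop[idx]

  # split post-burn-in intervals into contiguous blocks
  blocks <- split(seq_along(idx), cut(seq_along(idx), config$n_blocks,
                                      labels = FALSE))
  block_stat <- function(sel) {
    ii <- unlist(blocks[sel])
    ct <- sum(celltime[ii])
    c(mu = sum(deaths[ii]) / ct,
      fU = sum(siteU[ii]) / (host$N_S * ct),
      fH = sum(siteH[ii]) / (host$N_S * ct),
      fD = sum(siteD[ii]) / (host$N_S * ct))
  }
  # per-block growth increments (slope of the dilution-corrected log pop)
  block_slope <- function(sel) {
    num <- 0; den <- 0
    for (b in sel) {
      ii <- blocks[[b]]
      num <- num + lp[ii[length(ii)]] - lp[ii[1]]
      den <- den + tgrid[ii[length(ii)]] - tgrid[ii[1]]
    }
    num / den
  }

  est <- block_stat(seq_len(config$n_blocks))
  lambda_e_hat <- stats::coef(stats::lm(lp ~ tgrid))[["tgrid"]]

  boot <- with_seed(if (is.null(config$seed)) NULL else config$seed + 1L, {
    nb <- config$n_blocks
    reps <- 400L
    stat <- matrix(NA_real_, reps, 5)
    for (b in seq_len(reps)) {
      sel <- sample.int(nb, nb, replace = TRUE)
      stat[b, 1:4] <- block_stat(sel)
      stat[b, 5] <- block_slope(sel)
    }
    stat
  })
  se <- apply(boot, 2, stats::sd)

  structure(list(
    estimates = list(
      mu_hat = unname(est["mu"]), mu_se = se[1],
      lambda_e_hat = lambda_e_hat, lambda_e_se = se[5],
      p_qsd_hat = unname(est[c("fU", "fH", "fD")]), p_qsd_se = se[2:4]
    ),
    trajectory = traj, extinct = FALSE, ok = TRUE, config = config
  ), class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  if (!x$ok) {
    cat("Population simulation did not reach the estimation window",
        if (x$extinct) "(population went extinct)" else "", "\n")
    return(invisible(x))
  }
  e <- x$estimates
  cat(sprintf("mu_hat       = %.6g (se %.2g) min^-1\n", e$mu_hat, e$mu_se))
  cat(sprintf("lambda_e_hat = %.6g (se %.2g) min^-1\n",
              e$lambda_e_hat, e$lambda_e_se))
  cat(sprintf("p_qsd_hat    = (%.4g, %.4g, %.4g)\n",
              e$p_qsd_hat[1], e$p_qsd_hat[2], e$p_qsd_hat[3]))
  invisible(x)
}

#' Simulate first-phage-escape times
#'
#' Draws the first event time of an inhomogeneous Poisson process with rate
#' `rho * v * p_V * n0 * exp(lambda_e * t)` by transforming a unit-rate
#' exponential through the inverse of the cumulative hazard. This samples
#' the escape process directly from its mechanistic description and serves
#' as the distributional cross-check for the closed-form first-escape law.
#'
#' @param rm An [rm_params()] object.
#' @param host A [host_params()] object.
#' @param phage A [phage_params()] object.
#' @param n0 Initial bacterial population size.
#' @param reps Number of replicates.
#' @param seed Optional integer seed.
#' @return Vector of escape times (min); `Inf` where escape never occurs
#'   (possible when `lambda_e < 0`, and always when `p_V = 0`).
#' @export
simulate_first_escape <- function(rm, host, phage, n0 = 1, reps = 1,
                                  seed = NULL) {
  stopifnot(inherits(rm, "rm_params"), inherits(host, "host_params"),
            inherits(phage, "phage_params"), reps >= 1)
  p_V <- escape_probability(rm, phage$N_V)
  lambda_e <- effective_growth_rate(rm, host)
  a <- phage$rho * phage$v * p_V * n0
  ex <- with_seed(seed, stats::rexp(reps))
  if (a == 0) return(rep(Inf, reps))
  if (lambda_e == 0) return(ex / a)
  # invert Lambda(t) = a (e^{lambda_e t} - 1) / lambda_e at the sampled
  # exponential marks; marks beyond the total hazard never map to an event
  arg <- 1 + lambda_e * ex / a
  out <- rep(Inf, reps)
  ok <- arg > 0
  out[ok] <- log(arg[ok]) / lambda_e
  out
}
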