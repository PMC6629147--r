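#' Parameters for the bacteria-phage ecology model
#'
#' Deterministic ecology in the style of classic bacteria-phage chemostat
#' models, extended to track RM-carrying bacteria `B`, RM-free bacteria
#' `B0`, unmethylated (restrictable) phage `V_u`, and methylated (resistant)
#' phage `V_m`. Infection of an RM cell by an unmethylated phage is aborted
#' (phage removed, host survives) except with probability `p_V` the phage
#' escapes, lyses the host, and releases a methylated burst.
#'
#' @param delta Adsorption rate (per phage per cell per min).
#' @param beta Burst size (phage released per lysis).
#' @param d_V Spontaneous phage inactivation rate (min^-1).
#' @param K Bacterial carrying capacity (cells).
#' @param lambda_e Effective growth rate of the RM-carrying bacteria
#'   (min^-1); compute it with [effective_growth_rate()].
#' @param lambda Growth rate of RM-free bacteria (min^-1).
#' @param p_V Phage escape probability for the RM-carrying bacteria.
#' @return An object of class `ecology_params`.
#' @examples
#' ecology_params(delta = 1e-8, beta = 50, d_V = 0.01, K = 1e8,
#'                lambda_e = 0.015, lambda = 0.017, p_V = 1e-4)
#' @export
ecology_params <- function(delta, beta, d_V, K, lambda_e, lambda = lambda_e,
                           p_V) {
  stopifnot(delta >= 0, beta >= 0, d_V >= 0, K > 0,
            p_V >= 0, p_V <= 1)
  structure(list(delta = delta, beta = beta, d_V = d_V, K = K,
                 lambda_e = lambda_e, lambda = lambda, p_V = p_V),
            class = "ecology_params")
}

ecology_rhs <- function(t, y, p) {
  B <- y[1]; B0 <- y[2]; Vu <- y[3]; Vm <- y[4]
  crowd <- 1 - (B + B0) / p$K
  dB <- p$lambda_e * B * crowd - p$p_V * p$delta * B * Vu - p$delta * B * Vm
  dB0 <- p$lambda * B0 * crowd - p$delta * B0 * (Vu + Vm)
  dVu <- -p$delta * (B + B0) * Vu + p$beta * p$delta * B0 * Vu - p$d_V * Vu
  dVm <- p$beta * p$p_V * p$delta * B * Vu +
    (p$beta - 1) * p$delta * B * Vm +
    (p$beta - 1) * p$delta * B0 * Vm - p$d_V * Vm
  list(c(dB, dB0, dVu, dVm))
}

#' Integrate the bacteria-phage ecology
#'
#' Integrates the four-species system with a stiff-capable adaptive solver.
#' The absolute tolerance on phage densities is kept extremely small
#' (default 1e-30) so that phage populations that are biologically extinct
#' but mathematically positive remain representable: in an ODE description
#' phage never reach exactly zero, and whenever `p_V > 0` the methylated
#' phage eventually takes over.
#'
#' @param state0 Named numeric vector `c(B=, B0=, Vu=, Vm=)` of initial
#'   densities (all >= 0).
#' @param params An [ecology_params()] object.
#' @param t_grid Output times (min), increasing, starting at 0.
#' @param atol,rtol Solver tolerances.
#' @return A data frame with columns `time`, `B`, `B0`, `Vu`, `Vm`.
#' @examples
#' p <- ecology_params(delta = 1e-8, beta = 50, d_V = 0.01, K = 1e8,
#'                     lambda_e = 0.015, lambda = 0.017, p_V = 1e-4)
#' out <- simulate_ecology(c(B = 1e6, B0 = 0, Vu = 1e4, Vm = 0), p,
#'                         t_grid = seq(0, 2000, by = 100))
#' @export
simulate_ecology <- function(state0, params, t_grid,
                             atol = 1e-30, rtol = 1e-8) {
  stopifnot(inherits(params, "ecology_params"),
            all(c("B", "B0", "Vu", "Vm") %in% names(state0)),
            all(state0 >= 0), length(t_grid) >= 2, all(diff(t_grid) > 0))
  y0 <- state0[c("B", "B0", "Vu", "Vm")]
  out <- deSolve::lsoda(y = y0, times = t_grid, func = ecology_rhs,
                        parms = params, atol = atol, rtol = rtol,
                        maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0) {
    warning("ODE solver failed at t = ", max(out[, 1]),
            "; returning trajectory up to last good state")
  }
  df <- as.data.frame(out)
  names(df) <- c("time", "B", "B0", "Vu", "Vm")
  # clamp solver noise below atol to zero floor (state is non-negative)
  df[-1] <- lapply(df[-1], function(x) pmax(x, 0))
  df
}

#' Sweep ecology outcomes over enzyme-activity combinations
#'
#' For each `(r, m)` grid point, computes `p_V` and `lambda_e`, integrates
#' the ecology, and records whether methylated phage has overtaken
#' unmethylated phage by the end of the horizon and the minimum total phage
#' density reached. At long horizons the takeover outcome depends on the
#' ecological parameters but not on the RM activities: as long as
#' `p_V > 0`, methylated phage eventually dominates, however efficient the
#' RM system.
#'
#' @param r_grid,m_grid Enzyme-activity grids (min^-1).
#' @param host A [host_params()] object.
#' @param phage A [phage_params()] object.
#' @param eco_base An [ecology_params()] object supplying `delta`, `beta`,
#'   `d_V`, `K` (its `lambda_e`/`p_V` fields are overwritten per grid point).
#' @param state0 Initial state as in [simulate_ecology()].
#' @param t_max Integration horizon (min).
#' @param n_out Number of output times (log-spaced).
#' @param k,c_r,c_m RM-system count and costs applied at every grid point.
#' @return A data frame with one row per grid point: `r`, `m`, `p_V`,
#'   `lambda_e`, `takeover` (logical: `Vm > Vu` at `t_max`), `min_V`
#'   (minimum of `Vu + Vm` over the trajectory), `failed`.
#' @export
sweep_ecology <- function(r_grid, m_grid, host, phage, eco_base, state0,
                          t_max = 1e5, n_out = 60, k = 1, c_r = 0, c_m = 0,
                          atol = 1e-30, rtol = 1e-6) {
  stopifnot(inherits(eco_base, "ecology_params"))
  t_grid <- c(0, 10^seq(0, log10(t_max), length.out = n_out - 1))
  grid <- expand.grid(r = r_grid, m = m_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    rm <- rm_params(grid$r[i], grid$m[i], k = k, c_r = c_r, c_m = c_m)
    p_V <- escape_probability(rm, phage$N_V)
    lambda_e <- effective_growth_rate(rm, host)
    p <- ecology_params(delta = eco_base$delta, beta = eco_base$beta,
                        d_V = eco_base$d_V, K = eco_base$K,
                        lambda_e = lambda_e, lambda = host$lambda, p_V = p_V)
    tr <- tryCatch(simulate_ecology(state0, p, t_grid, atol = atol,
                                    rtol = rtol),
                   warning = function(w) NULL, error = function(e) NULL)
    if (is.null(tr)) {
      return(data.frame(r = rm$r, m = rm$m, p_V = p_V, lambda_e = lambda_e,
                        takeover = NA, min_V = NA_real_, failed = TRUE))
    }
    last <- tr[nrow(tr), ]
    data.frame(r = rm$r, m = rm$m, p_V = p_V, lambda_e = lambda_e,
               takeover = last$Vm > last$Vu,
               min_V = min(tr$Vu + tr$Vm), failed = FALSE)
  })
  do.call(rbind, res)
}
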