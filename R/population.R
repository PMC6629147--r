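#' Population self-restriction rate
#'
#' The per-cell rate at which a growing population loses cells to accidental
#' cutting of the host's own restriction sites. With the methylation state of
#' surviving cells at its quasi-stationary distribution, each of the `N_S`
#' sites carries a constant cut hazard `-gamma1`, so the per-cell rate is
#' `mu = -gamma1 * N_S`. Equivalently `mu = N_S / E[tau_i]` with the expected
#' per-site waiting time evaluated at the QSD; both forms are computed and
#' cross-checked here to 1e-8 relative.
#'
#' @param rm An [rm_params()] object. `mu` is the per-system rate; it does not
#'   use `k` (see [effective_growth_rate()] for the multi-system total).
#' @param host A [host_params()] object.
#' @return Self-restriction rate (min^-1, >= 0).
#' @examples
#' self_restriction_rate(rm_params(0.1, 0.05), host_params(0.017, 5))
#' @export
self_restriction_rate <- function(rm, host) {
  stopifnot(inherits(rm, "rm_params"), inherits(host, "host_params"))
  if (rm$r == 0) return(0)
  if (host$lambda == 0) {
    # fully methylated steady state: sites never demethylate, no hazard
    return(0)
  }
  gen <- site_generator(rm, host)
  q <- quasi_stationary(gen)
  mu_eig <- -q$gamma1 * host$N_S
  et <- expected_site_time(gen, q$p_qsd)
  if (is.finite(et) && mu_eig > 0) {
    mu_inv <- host$N_S / et
    # absolute floor: eigenvalues are only accurate to ~eps * ||B||, which
    # dominates when gamma1 is many orders below the largest rates
    tol <- 1e-8 * mu_eig +
      32 * .Machine$double.eps * (rm$r + rm$m + host$lambda) * host$N_S
    if (abs(mu_inv - mu_eig) > tol)
      stop(sprintf(
        "internal inconsistency: eigenvalue form mu = %.12g but inverse-mean form mu = %.12g",
        mu_eig, mu_inv))
  }
  max(mu_eig, 0)
}

#' Effective population growth rate
#'
#' Replication minus the per-cell losses from running `k` equivalent RM
#' systems: `lambda_e = lambda - k * (mu(r, m, lambda) + c_r * r + c_m * m)`.
#' Each system contributes its own self-restriction rate and its
#' enzyme-expression cost. With `k = 1` and zero costs this reduces to
#' `lambda - mu`. Negative values are legal and describe a shrinking
#' population.
#'
#' @inheritParams self_restriction_rate
#' @return Effective growth rate (min^-1), possibly negative.
#' @examples
#' effective_growth_rate(rm_params(0.1, 0.05), host_params(0.017, 5))
#' @export
effective_growth_rate <- function(rm, host) {
  stopifnot(inherits(rm, "rm_params"), inherits(host, "host_params"))
  mu <- self_restriction_rate(rm, host)
  host$lambda - rm$k * (mu + rm$c_r * rm$r + rm$c_m * rm$m)
}

#' Expected exponential growth
#'
#' Expected population size under the birth-death description of growth with
#' self-restriction: `n(t) = n0 * exp(lambda_e * t)`.
#'
#' @param n0 Initial population size (>= 0).
#' @param lambda_e Effective growth rate (min^-1).
#' @param t Time or vector of times (min, >= 0).
#' @return Expected population sizes, one per element of `t`.
#' @examples
#' grow(100, 0.01, 100)
#' @export
grow <- function(n0, lambda_e, t) {
  stopifnot(is.numeric(n0), n0 >= 0, is.numeric(t), all(t >= 0),
            is.numeric(lambda_e), length(lambda_e) == 1L)
  n0 * exp(lambda_e * t)
}

#' Growth summary for a parameter set
#'
#' Convenience wrapper collecting the population-scale quantities for one
#' parameter set: self-restriction rate `mu`, effective growth rate
#' `lambda_e`, and (when phage parameters are supplied) the phage escape
#' probability `p_V`.
#'
#' @inheritParams self_restriction_rate
#' @param phage Optional [phage_params()] object.
#' @return An object of class `growth_summary`.
#' @export
growth_summary <- function(rm, host, phage = NULL) {
  mu <- self_restriction_rate(rm, host)
  lambda_e <- host$lambda - rm$k * (mu + rm$c_r * rm$r + rm$c_m * rm$m)
  pV <- if (is.null(phage)) NA_real_ else escape_probability(rm, phage$N_V)
  structure(list(mu = mu, lambda_e = lambda_e, p_V = pV,
                 rm = rm, host = host),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf("mu = %.6g min^-1, lambda_e = %.6g min^-1", x$mu, x$lambda_e))
  if (!is.na(x$p_V)) cat(sprintf(", p_V = %.6g", x$p_V))
  cat("\n")
  invisible(x)
}
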