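#' Generator of the single-site methylation chain
#'
#' A restriction site on the host genome is a three-state continuous-time
#' Markov chain over the transient states (unmethylated, hemi-methylated,
#' doubly-methylated) with one absorbing state: the site is cut, killing the
#' cell. Methylation adds methyl groups at rate `m` (unmethylated -> hemi,
#' hemi -> doubly); replication at rate `lambda` removes them (doubly -> hemi
#' at rate `lambda`, hemi -> unmethylated at rate `lambda / 2`, since only one
#' daughter copy of a hemi-methylated site is bare); cutting occurs from the
#' unmethylated state at rate `r`.
#'
#' The state ordering is fixed as (unmethylated, hemi, doubly) throughout the
#' package, matching the methylation distribution vector `(p0, p1, p2)`.
#'
#' @param rm An [rm_params()] object (only `r` and `m` are used here).
#' @param host A [host_params()] object (only `lambda` is used here).
#'
#' @return An object of class `site_generator`: a list with the 3x3 transient
#'   sub-generator `B` and the length-3 absorption-rate vector `c1 = (r, 0, 0)`.
#'   Row sums of `B` equal `-c1`.
#' @examples
#' gen <- site_generator(rm_params(0.1, 0.05), host_params(0.017, 5))
#' gen$B
#' @export
site_generator <- function(rm, host) {
  stopifnot(inherits(rm, "rm_params"), inherits(host, "host_params"))
  r <- rm$r
  m <- rm$m
  lam <- host$lambda
  B <- matrix(c(-(r + m),        m,               0,
                lam / 2, -(m + lam / 2),          m,
                0,              lam,           -lam),
              nrow = 3, ncol = 3, byrow = TRUE,
              dimnames = list(c("U", "H", "D"), c("U", "H", "D")))
  structure(list(B = B, c1 = c(r, 0, 0), r = r, m = m, lambda = lam),
            class = "site_generator")
}

#' @export
print.site_generator <- function(x, ...) {
  cat("Single-site methylation generator (states U, H, D; absorption = cut)\n")
  print(x$B)
  cat("absorption rates c1:", x$c1, "\n")
  invisible(x)
}

#' Methylation configuration vector
#'
#' Validates and normalizes a probability vector `(p0, p1, p2)` over the site
#' states (unmethylated, hemi-methylated, doubly-methylated).
#'
#' @param p0,p1,p2 Non-negative probabilities summing to 1.
#' @return A named numeric vector of length 3.
#' @examples
#' methylation_distribution(0, 0, 1)   # fully protected site
#' @export
methylation_distribution <- function(p0, p1, p2) {
  p <- c(U = p0, H = p1, D = p2)
  stopifnot(all(is.finite(p)), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-12)
    stop("methylation probabilities must sum to 1 (got ", sum(p), ")")
  p
}

as_pq <- function(pQ) {
  pQ <- as.numeric(pQ)
  stopifnot(length(pQ) == 3L, all(is.finite(pQ)), all(pQ >= -1e-15))
  if (abs(sum(pQ) - 1) > 1e-9)
    stop("initial methylation configuration must sum to 1")
  pmax(pQ, 0)
}

#' Phase-type density of the time to a site's first cut
#'
#' The waiting time until a given restriction site is cut follows a
#' phase-type law: `f(tau) = pQ %*% expm(B * tau) %*% c1`, where `pQ` is the
#' initial methylation configuration.
#'
#' @param gen A [site_generator()].
#' @param pQ Initial methylation configuration, length-3 probability vector
#'   ordered (unmethylated, hemi, doubly).
#' @param tau Vector of non-negative times (min).
#' @return Density values (min^-1), one per element of `tau`.
#' @examples
#' gen <- site_generator(rm_params(0.1, 0.05), host_params(0.017, 5))
#' phase_type_pdf(gen, c(0, 0, 1), c(0, 10, 100))
#' @export
phase_type_pdf <- function(gen, pQ, tau) {
  stopifnot(inherits(gen, "site_generator"))
  pQ <- as_pq(pQ)
  if (any(tau < 0)) stop("tau must be non-negative")
  vapply(tau, function(t) {
    E <- as.matrix(Matrix::expm(gen$B * t))
    max(0, drop(pQ %*% E %*% gen$c1))
  }, numeric(1))
}

#' Phase-type distribution function of the time to a site's first cut
#'
#' `F(tau) = 1 - pQ %*% expm(B * tau) %*% 1`: one minus the probability of
#' still being in a transient (uncut) state at time `tau`.
#'
#' @inheritParams phase_type_pdf
#' @return Probabilities in `[0, 1]`, one per element of `tau`.
#' @export
phase_type_cdf <- function(gen, pQ, tau) {
  stopifnot(inherits(gen, "site_generator"))
  pQ <- as_pq(pQ)
  if (any(tau < 0)) stop("tau must be non-negative")
  vapply(tau, function(t) {
    E <- as.matrix(Matrix::expm(gen$B * t))
    min(1, max(0, 1 - sum(pQ %*% E)))
  }, numeric(1))
}

#' Expected time until a site's first cut
#'
#' `E[tau_i] = -pQ %*% solve(B) %*% 1`. When the chain has no path to
#' absorption from the support of `pQ` (for example `r=0`, or `lambda = 0`
#' starting from a protected site) the mean is infinite; this is returned as
#' `Inf` rather than raised as an error, because boundary parameter values are
#' routinely visited by optimization sweeps.
#'
#' @inheritParams phase_type_pdf
#' @return Mean waiting time (min); `Inf` in the degenerate no-absorption
#'   cases.
#' @examples
#' gen <- site_generator(rm_params(0.1, 0), host_params(0, 5))
#' expected_site_time(gen, c(1, 0, 0))  # pure exponential: 1 / r
#' @export
expected_site_time <- function(gen, pQ) {
  stopifnot(inherits(gen, "site_generator"))
  pQ <- as_pq(pQ)
  if (gen$r == 0) return(Inf)
  if (gen$lambda == 0) {
    # no replication: methylated sites never demethylate, so any mass that
    # starts protected (or gets methylated before a cut) escapes forever
    if (sum(pQ[2:3]) > 0 || gen$m > 0) return(Inf)
    return(1 / gen$r)
  }
  inv <- tryCatch(solve(gen$B), error = function(e) NULL)
  if (is.null(inv)) return(Inf)
  val <- -drop(pQ %*% inv %*% rep(1, 3))
  if (!is.finite(val) || val <= 0) Inf else val
}

#' Quasi-stationary methylation distribution of surviving lineages
#'
#' In a steadily growing population, cells with unmethylated sites are
#' preferentially removed by self-restriction while replication keeps
#' producing fresh unmethylated sites. The methylation configuration of a
#' randomly chosen live cell converges to the quasi-stationary distribution
#' (QSD) of the single-site chain: the left eigenvector of `B` associated
#' with its dominant (largest, real, non-positive) eigenvalue `gamma1`,
#' normalized to a probability vector. Conditioned on survival the hazard of
#' a cut becomes constant, `p_qsd %*% c1 = -gamma1`, so the per-site waiting
#' time is exactly exponential with rate `-gamma1`.
#'
#' @param gen A [site_generator()].
#' @return An object of class `qsd_result`: list with `p_qsd` (named length-3
#'   probability vector) and `gamma1` (dominant eigenvalue, min^-1, <= 0).
#' @examples
#' gen <- site_generator(rm_params(0.1, 0.05), host_params(0.017, 5))
#' quasi_stationary(gen)
#' @export
quasi_stationary <- function(gen) {
  stopifnot(inherits(gen, "site_generator"))
  e <- eigen(t(gen$B))
  i <- which.max(Re(e$values))
  gamma1 <- e$values[i]
  vec <- e$vectors[, i]
  if (max(abs(Im(c(gamma1, vec)))) > 1e-8)
    stop("dominant eigenpair of B is not numerically real; ",
         "generator may be invalid: gamma1 = ", format(gamma1))
  gamma1 <- Re(gamma1)
  vec <- Re(vec)
  if (sum(vec) < 0) vec <- -vec
  if (any(vec < -1e-10 * max(abs(vec))))
    stop("dominant left eigenvector of B has negative entries beyond ",
         "tolerance; cannot form a quasi-stationary distribution")
  vec <- pmax(vec, 0)
  p <- vec / sum(vec)
  names(p) <- c("U", "H", "D")
  structure(list(p_qsd = p, gamma1 = min(gamma1, 0)), class = "qsd_result")
}

#' @export
print.qsd_result <- function(x, ...) {
  cat(sprintf("Quasi-stationary site distribution: U = %.4g, H = %.4g, D = %.4g\n",
              x$p_qsd[1], x$p_qsd[2], x$p_qsd[3]))
  cat(sprintf("Dominant eigenvalue gamma1 = %.6g min^-1 (site cut hazard %.6g)\n",
              x$gamma1, -x$gamma1))
  invisible(x)
}
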