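#' Restriction-modification enzyme parameters
#'
#' Bundles the activities of the two RM enzymes together with the number of
#' concurrently active RM systems and their growth-rate costs. Activities are
#' totals over all enzyme molecules in the cell, in units of min^-1.
#'
#' @param r Total restriction-endonuclease activity (min^-1, >= 0). An
#'   unmethylated site is cut (lethally) at rate `r`.
#' @param m Total methyltransferase activity (min^-1, >= 0). An unmethylated or
#'   hemi-methylated site gains a methyl group at rate `m`.
#' @param k Number of concurrently active, equivalent RM systems (integer >= 1).
#' @param c_r,c_m Growth-rate cost per unit enzyme activity (dimensionless
#'   multipliers, >= 0); the cost term in the effective growth rate is
#'   `c_r * r + c_m * m` per system.
#'
#' @return An object of class `rm_params`.
#' @examples
#' rm_params(r = 0.1, m = 0.05)
#' @export
rm_params <- function(r, m, k = 1L, c_r = 0, c_m = 0) {
  stopifnot(
    is.numeric(r), length(r) == 1L, is.finite(r), r >= 0,
    is.numeric(m), length(m) == 1L, is.finite(m), m >= 0,
    is.numeric(k), length(k) == 1L, is.finite(k), k >= 1, k == round(k),
    is.numeric(c_r), length(c_r) == 1L, is.finite(c_r), c_r >= 0,
    is.numeric(c_m), length(c_m) == 1L, is.finite(c_m), c_m >= 0
  )
  structure(
    list(r = as.numeric(r), m = as.numeric(m), k = as.integer(k),
         c_r = as.numeric(c_r), c_m = as.numeric(c_m)),
    class = "rm_params"
  )
}

#' Host-cell parameters
#'
#' @param lambda Replication rate of the bacterial host (min^-1, >= 0).
#'   Replication demethylates: each doubly-methylated site is turned
#'   hemi-methylated at rate `lambda` and each hemi-methylated site turns
#'   unmethylated at rate `lambda / 2` (only one of the two daughter copies
#'   of a hemi-methylated site is unmethylated).
#' @param N_S Number of restriction sites on the host genome (integer >= 1).
#'
#' @return An object of class `host_params`.
#' @examples
#' host_params(lambda = 0.017, N_S = 5)
#' @export
host_params <- function(lambda, N_S) {
  stopifnot(
    is.numeric(lambda), length(lambda) == 1L, is.finite(lambda), lambda >= 0,
    is.numeric(N_S), length(N_S) == 1L, is.finite(N_S), N_S >= 1,
    N_S == round(N_S)
  )
  structure(
    list(lambda = as.numeric(lambda), N_S = as.integer(N_S)),
    class = "host_params"
  )
}

#' Phage and encounter-process parameters
#'
#' @param N_V Number of restriction sites on the phage genome (integer >= 1).
#' @param rho Per-phage per-cell encounter/infection rate (min^-1 per phage
#'   per cell).
#' @param v Phage population size, assumed approximately constant until the
#'   first escape event (>= 0).
#' @param c_mut Rate at which a single bacterial cell acquires a
#'   phage-resistance mutation (min^-1, >= 0).
#'
#' @return An object of class `phage_params`.
#' @examples
#' phage_params(N_V = 5, rho = 1, v = 1)
#' @export
phage_params <- function(N_V, rho = 1, v = 1, c_mut = 0) {
  stopifnot(
    is.numeric(N_V), length(N_V) == 1L, is.finite(N_V), N_V >= 1,
    N_V == round(N_V),
    is.numeric(rho), length(rho) == 1L, is.finite(rho), rho >= 0,
    is.numeric(v), length(v) == 1L, is.finite(v), v >= 0,
    is.numeric(c_mut), length(c_mut) == 1L, is.finite(c_mut), c_mut >= 0
  )
  structure(
    list(N_V = as.integer(N_V), rho = as.numeric(rho), v = as.numeric(v),
         c_mut = as.numeric(c_mut)),
    class = "phage_params"
  )
}

#' @export
print.rm_params <- function(x, ...) {
  cat(sprintf("RM system: r = %g min^-1, m = %g min^-1, k = %d, c_r = %g, c_m = %g\n",
              x$r, x$m, x$k, x$c_r, x$c_m))
  invisible(x)
}

#' @export
print.host_params <- function(x, ...) {
  cat(sprintf("Host: lambda = %g min^-1, N_S = %d sites\n", x$lambda, x$N_S))
  invisible(x)
}

#' @export
print.phage_params <- function(x, ...) {
  cat(sprintf("Phage: N_V = %d sites, rho = %g, v = %g, c_mut = %g\n",
              x$N_V, x$rho, x$v, x$c_mut))
  invisible(x)
}

#' Named parameter regimes
#'
#' Returns the parameter bundles used throughout the package's worked
#' examples: the `"reference"` regime (r = 0.1 min^-1, m = 0.05 min^-1,
#' lambda = 0.017 min^-1) sits in the transition region where self-restriction
#' materially slows growth; `"small"` scales the enzyme activities down
#' 2e-fold and `"large"` scales them up e-fold; `"fig_sweep"` is the
#' realistic-genome setting for Pareto sweeps (N_S = 599, N_V = 5,
#' cost 1e-5); `"ecoli"` is the E. coli/EcoRI calibration input
#' (cost 3.7e-7, growth-reduction budget 1e-3 min^-1).
#'
#' @param name One of `"reference"`, `"small"`, `"large"`, `"fig_sweep"`,
#'   `"ecoli"`.
#'
#' @return A list with components `rm`, `host`, and (where meaningful)
#'   `phage`, `cost`, `budget`.
#' @examples
#' fixture_params("reference")
#' @export
fixture_params <- function(name = c("reference", "small", "large",
                                    "fig_sweep", "ecoli")) {
  name <- match.arg(name)
  r_ref <- 0.1
  m_ref <- 0.05
  lam_ref <- 0.017
  switch(name,
    reference = list(
      rm = rm_params(r = r_ref, m = m_ref),
      host = host_params(lambda = lam_ref, N_S = 5L)
    ),
    small = list(
      rm = rm_params(r = r_ref / (2 * exp(1)), m = m_ref / (2 * exp(1))),
      host = host_params(lambda = lam_ref, N_S = 5L)
    ),
    large = list(
      rm = rm_params(r = r_ref * exp(1), m = m_ref * exp(1)),
      host = host_params(lambda = lam_ref, N_S = 5L)
    ),
    fig_sweep = list(
      host = host_params(lambda = lam_ref, N_S = 599L),
      phage = phage_params(N_V = 5L),
      cost = 1e-5
    ),
    ecoli = list(
      host = host_params(lambda = lam_ref, N_S = 599L),
      phage = phage_params(N_V = 5L),
      cost = 3.7e-7,
      budget = 1e-3
    )
  )
}
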