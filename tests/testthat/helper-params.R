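# Shared fixtures and small independent oracles used across test files.

ref <- fixture_params("reference")
ref_gen <- site_generator(ref$rm, ref$host)

# direct construction of the generator, independent of site_generator()
oracle_B <- function(r, m, lam) {
  matrix(c(-(r + m), m, 0,
           lam / 2, -(m + lam / 2), m,
           0, lam, -lam), 3, 3, byrow = TRUE)
}

# brute-force O(n^2) non-dominated filter (maximize both objectives)
oracle_front <- function(points) {
  n <- nrow(points)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (points$lambda_e[j] >= points$lambda_e[i] &&
          points$n_s[j] >= points$n_s[i] &&
          (points$lambda_e[j] > points$lambda_e[i] ||
           points$n_s[j] > points$n_s[i])) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  points[!dominated, , drop = FALSE]
}

# naive single-cell self-restriction rate: site-state law equilibrated
# without the absorbing state (the r-free stationary distribution), then
# exposed to cutting at rate r from the unmethylated state
oracle_naive_mu <- function(r, m, lambda, N_S) {
  gen0 <- site_generator(rm_params(0, m), host_params(lambda, N_S))
  p_stat <- quasi_stationary(gen0)$p_qsd
  N_S * r * p_stat[["U"]]
}

random_rates <- function(n, seed) {
  set.seed(seed)
  data.frame(r = 10^runif(n, -3, 2), m = 10^runif(n, -3, 2),
             lambda = 10^runif(n, -3, 0))
}
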