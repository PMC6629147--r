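test_that("escape probability follows the per-site race closed form", {
  expect_equal(escape_probability(rm_params(0.2, 0.2), 5), 2^-5)
  expect_equal(escape_probability(rm_params(0.1, 0), 5), 0)
  expect_equal(escape_probability(rm_params(0, 0.05), 5), 1)
  expect_equal(escape_probability(rm_params(0, 0), 5), 1)
  # k systems multiply the exponent
  expect_equal(escape_probability(rm_params(0.1, 0.05, k = 3), 5),
               (0.05 / 0.15)^15)

  # Monte-Carlo oracle: N_V sites race methylation against cutting
  set.seed(11)
  n_mc <- 1e5
  r <- 0.1; m <- 0.05; N_V <- 5
  meth_first <- matrix(stats::rexp(n_mc * N_V, m) <
                       stats::rexp(n_mc * N_V, r), ncol = N_V)
  p_hat <- mean(rowSums(meth_first) == N_V)
  p_true <- escape_probability(rm_params(r, m), N_V)
  se <- sqrt(p_true * (1 - p_true) / n_mc)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("escape probability is monotone in both activities", {
  m_grid <- 10^seq(-2, 1, length.out = 7)
  pv_m <- vapply(m_grid, function(m)
    escape_probability(rm_params(0.1, m), 5), numeric(1))
  expect_true(all(diff(pv_m) > 0))
  r_grid <- 10^seq(-2, 1, length.out = 7)
  pv_r <- vapply(r_grid, function(r)
    escape_probability(rm_params(r, 0.05), 5), numeric(1))
  expect_true(all(diff(pv_r) < 0))
})

test_that("first-escape density reduces to an exponential and has correct mass", {
  phage <- phage_params(N_V = 5)
  tau <- c(0, 0.5, 2, 10, 40)

  mod0 <- escape_time_model(phage = phage, n0 = 10, p_V = 0.02, lambda_e = 0)
  expect_equal(escape_time_pdf(mod0, tau), mod0$a * exp(-mod0$a * tau),
               tolerance = 1e-10)

  modp <- escape_time_model(phage = phage, n0 = 5, p_V = 0.01, lambda_e = 0.02)
  expect_equal(integrate(function(t) escape_time_pdf(modp, t), 0, Inf,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)

  modn <- escape_time_model(phage = phage, n0 = 5, p_V = 0.01, lambda_e = -0.03)
  mass <- integrate(function(t) escape_time_pdf(modn, t), 0, Inf,
                    rel.tol = 1e-12)$value
  expect_equal(mass, 1 - exp(modn$a / modn$lambda_e), tolerance = 1e-8)

  expect_error(escape_time_pdf(modp, -1))
})

test_that("cdf and quantile are exact inverses", {
  phage <- phage_params(N_V = 5)
  set.seed(22)
  for (i in 1:20) {
    mod <- escape_time_model(phage = phage, n0 = 10^runif(1, 0, 3),
                             p_V = 10^runif(1, -6, -1),
                             lambda_e = runif(1, -0.05, 0.05))
    expect_equal(escape_time_quantile(mod, 0), 0)
    u <- runif(5, 0, 0.99)
    attainable <- if (mod$lambda_e < 0)
      u < 1 - exp(mod$a / mod$lambda_e) else rep(TRUE, 5)
    tq <- escape_time_quantile(mod, u)
    expect_true(all(is.infinite(tq[!attainable])))
    expect_equal(escape_time_cdf(mod, tq[attainable]), u[attainable],
                 tolerance = 1e-10)
  }
  # exponential special case: u = 1 - 1/e at a = 1 gives tau = 1
  mod <- escape_time_model(phage = phage, n0 = 1, p_V = 1, lambda_e = 0)
  expect_equal(escape_time_quantile(mod, 1 - exp(-1)), 1, tolerance = 1e-12)
})

test_that("sampling is reproducible and distributed per the closed-form law", {
  phage <- phage_params(N_V = 5)
  mod <- escape_time_model(phage = phage, n0 = 3, p_V = 0.004,
                           lambda_e = 0.01)
  s1 <- sample_escape_times(mod, 1000, seed = 5)
  s2 <- sample_escape_times(mod, 1000, seed = 5)
  expect_identical(s1, s2)

  s <- sample_escape_times(mod, 2e4, seed = 6)
  ks <- suppressWarnings(
    stats::ks.test(s, function(q) escape_time_cdf(mod, q)))
  expect_gt(ks$p.value, 0.01)

  # lambda_e = 0: exponential mean 1/a
  mod0 <- escape_time_model(phage = phage, n0 = 3, p_V = 0.004, lambda_e = 0)
  s0 <- sample_escape_times(mod0, 2e4, seed = 7)
  expect_lt(abs(mean(s0) - 1 / mod0$a), 3 * sd(s0) / sqrt(length(s0)))
})

test_that("performance metrics match their closed forms in special cases", {
  host <- host_params(0.017, 5)
  rm <- rm_params(0.1, 0.05)

  pm0 <- performance_metrics(rm, host, phage_params(N_V = 5, c_mut = 0))
  expect_equal(pm0$p_mut_first, 0)
  expect_equal(pm0$expected_mutations, 0)

  # symmetric race: c_tilde equal to p_V gives a fair coin
  p_V <- escape_probability(rm, 5)
  pm_sym <- performance_metrics(rm, host,
                                phage_params(N_V = 5, c_mut = p_V))
  expect_equal(pm_sym$p_mut_first, 0.5, tolerance = 1e-12)

  # perfect immunity: escape never happens
  pm_inf <- performance_metrics(rm_params(0.1, 0), host,
                                phage_params(N_V = 5, c_mut = 1e-6))
  expect_identical(pm_inf$n_s, Inf)
})

test_that("metrics agree with a competing-risks simulation and ignore n0", {
  host <- host_params(0.017, 5)
  rm <- rm_params(0.1, 0.05)
  p_V <- escape_probability(rm, 5)
  lambda_e <- effective_growth_rate(rm, host)
  c_mut <- 0.004
  phage <- phage_params(N_V = 5, c_mut = c_mut)
  pm <- performance_metrics(rm, host, phage)

  set.seed(33)
  n_mc <- 1e5
  for (n0 in c(1, 10, 1000)) {
    # first event of each inhomogeneous Poisson process with rate
    # proportional to n(t) = n0 exp(lambda_e t), via hazard inversion
    first_event <- function(rate0) {
      e <- stats::rexp(n_mc)
      log(1 + lambda_e * e / (rate0 * n0)) / lambda_e
    }
    tp <- first_event(p_V)          # rho = v = 1
    tmut <- first_event(c_mut)
    growth <- n0 * exp(lambda_e * tp) - n0
    expect_lt(abs(mean(growth) - pm$n_s),
              3 * sd(growth) / sqrt(n_mc))
    p_hat <- mean(tmut < tp)
    expect_lt(abs(p_hat - pm$p_mut_first),
              3 * sqrt(p_hat * (1 - p_hat) / n_mc))
    # mutation counts up to the first escape are Poisson in the
    # integrated population size
    muts <- stats::rpois(n_mc, c_mut * (growth + 0) / lambda_e)
    expect_lt(abs(mean(muts) - pm$expected_mutations),
              3 * sd(muts) / sqrt(n_mc))
  }
})

test_that("larger hazard parameters shift escape stochastically earlier", {
  phage <- phage_params(N_V = 5)
  base <- escape_time_model(phage = phage, n0 = 10, p_V = 1e-3,
                            lambda_e = 0.01)
  u <- seq(0.05, 0.95, by = 0.1)
  q_base <- escape_time_quantile(base, u)
  for (mod in list(
    escape_time_model(phage = phage, n0 = 20, p_V = 1e-3, lambda_e = 0.01),
    escape_time_model(phage = phage, n0 = 10, p_V = 2e-3, lambda_e = 0.01),
    escape_time_model(phage = phage, n0 = 10, p_V = 1e-3, lambda_e = 0.02),
    escape_time_model(phage = phage_params(N_V = 5, rho = 2), n0 = 10,
                      p_V = 1e-3, lambda_e = 0.01))) {
    expect_true(all(escape_time_quantile(mod, u) < q_base))
  }
})
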