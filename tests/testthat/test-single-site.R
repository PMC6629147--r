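test_that("site generator reproduces the methylation/cutting rate structure", {
  expect_equal(unname(ref_gen$B),
               rbind(c(-0.15, 0.05, 0),
                     c(0.0085, -0.0585, 0.05),
                     c(0, 0.017, -0.017)))
  expect_equal(ref_gen$c1, c(0.1, 0, 0))

  zero <- site_generator(rm_params(0, 0), host_params(0, 1))
  expect_true(all(zero$B == 0))
  expect_equal(zero$c1, rep(0, 3))

  expect_error(rm_params(-0.1, 0.05))
  expect_error(host_params(-1, 5))
})

test_that("generator row sums equal minus the absorption vector for random rates", {
  draws <- random_rates(25, seed = 101)
  for (i in seq_len(nrow(draws))) {
    gen <- site_generator(rm_params(draws$r[i], draws$m[i]),
                          host_params(draws$lambda[i], 5))
    expect_equal(unname(drop(gen$B %*% rep(1, 3))), -gen$c1, tolerance = 1e-12)
    expect_equal(unname(gen$B), oracle_B(draws$r[i], draws$m[i], draws$lambda[i]))
  }
})

test_that("phase-type density has the correct boundary values and unit mass", {
  # at tau = 0 the matrix exponential is the identity: f(0) = p0 * r
  expect_equal(phase_type_pdf(ref_gen, c(0.3, 0.3, 0.4), 0), 0.3 * 0.1)
  expect_equal(phase_type_pdf(ref_gen, c(0, 0, 1), 0), 0)
  expect_error(phase_type_pdf(ref_gen, c(0, 0, 1), -1))

  # absorption is certain when r > 0 and lambda > 0: density integrates to 1
  total <- integrate(function(t) phase_type_pdf(ref_gen, c(0, 0, 1), t),
                     0, Inf, rel.tol = 1e-9)
  expect_equal(total$value, 1, tolerance = 1e-6)
})

test_that("cdf is a proper distribution function consistent with the density", {
  pQ <- c(0, 0, 1)
  tau <- c(0, 1, 5, 20, 100, 500, 2000, 10000)
  Fv <- phase_type_cdf(ref_gen, pQ, tau)
  expect_equal(Fv[1], 0)
  expect_true(all(diff(Fv) >= 0))
  expect_true(all(Fv >= 0 & Fv <= 1))

  # finite-difference derivative of the cdf matches the density
  h <- 1e-4
  for (t in c(10, 100, 700)) {
    deriv <- (phase_type_cdf(ref_gen, pQ, t + h) -
              phase_type_cdf(ref_gen, pQ, t - h)) / (2 * h)
    expect_equal(deriv, phase_type_pdf(ref_gen, pQ, t), tolerance = 1e-6)
  }

  # no absorption channel: cdf identically zero
  gen0 <- site_generator(rm_params(0, 0.05), host_params(0.017, 5))
  expect_equal(phase_type_cdf(gen0, pQ, c(10, 1e4)), c(0, 0))
})

test_that("expected waiting time matches closed forms and quadrature", {
  # m = 0 from an unmethylated start: plain exponential race, mean 1/r
  gen <- site_generator(rm_params(0.25, 0), host_params(0.017, 5))
  expect_equal(expected_site_time(gen, c(1, 0, 0)), 1 / 0.25)

  # no absorbing transition: infinite mean, reported as a sentinel
  gen0 <- site_generator(rm_params(0, 0.05), host_params(0.017, 5))
  expect_identical(expected_site_time(gen0, c(0, 0, 1)), Inf)

  # protected start with no replication: mass never demethylates
  genl0 <- site_generator(rm_params(0.1, 0.05), host_params(0, 5))
  expect_identical(expected_site_time(genl0, c(0, 0, 1)), Inf)

  # reference parameters: agree with the quadrature of tau * f(tau)
  mean_quad <- integrate(function(t) t * phase_type_pdf(ref_gen, c(0, 0, 1), t),
                         0, Inf, rel.tol = 1e-10)$value
  expect_equal(expected_site_time(ref_gen, c(0, 0, 1)), mean_quad,
               tolerance = 1e-6)
})

test_that("quasi-stationary distribution has the closed-form degenerate limits", {
  # r = 0: no absorption, QSD is the stationary law with balance
  # p0 = (lambda / (2 m)) p1 and p2 = (m / lambda) p1
  gen <- site_generator(rm_params(0, 0.05), host_params(0.017, 5))
  q <- quasi_stationary(gen)
  expect_equal(q$gamma1, 0, tolerance = 1e-14)
  expect_equal(q$p_qsd[["U"]], (0.017 / (2 * 0.05)) * q$p_qsd[["H"]],
               tolerance = 1e-10)
  expect_equal(q$p_qsd[["D"]], (0.05 / 0.017) * q$p_qsd[["H"]],
               tolerance = 1e-10)

  # m = 0: triangular generator, gamma1 = -min(r, lambda / 2)
  for (r in c(0.002, 0.3)) {
    gen <- site_generator(rm_params(r, 0), host_params(0.017, 5))
    expect_equal(quasi_stationary(gen)$gamma1, -min(r, 0.017 / 2),
                 tolerance = 1e-12)
  }
})

test_that("starting from the QSD the waiting time is a pure exponential", {
  for (fx in list(fixture_params("small"), ref, fixture_params("large"))) {
    gen <- site_generator(fx$rm, fx$host)
    q <- quasi_stationary(gen)
    expect_equal(unname(sum(q$p_qsd * gen$c1)), -q$gamma1, tolerance = 1e-10)
    tau <- c(0, 1, 10, 50, 200, 1000)
    expect_equal(phase_type_pdf(gen, q$p_qsd, tau),
                 (-q$gamma1) * exp(q$gamma1 * tau), tolerance = 1e-8)
  }
})

test_that("raising restriction activity never delays self-restriction", {
  r_grid <- 10^seq(-3, 1, length.out = 9)
  means <- vapply(r_grid, function(r) {
    gen <- site_generator(rm_params(r, 0.05), host_params(0.017, 5))
    expected_site_time(gen, c(0, 0, 1))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})
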