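test_that("correlation sums equal a brute-force pair count", {
  withr::with_seed(21, states <- matrix(runif(600), 300, 2))
  eps <- c(0.05, 0.1, 0.2, 0.5, 1.5)
  cc <- correlation_sum(states, epsilons = eps, theiler = 3)
  # O(n^2) oracle
  cnt <- numeric(length(eps)); np <- 0
  for (i in 1:299) for (j in (i + 1):300) {
    if (j - i <= 3) next
    np <- np + 1
    d <- brute_dist(states, i, j)
    cnt <- cnt + (d <= eps)
  }
  expect_equal(cc$counts, cnt)
  expect_equal(cc$n_pairs, np)
  expect_equal(cc$C[length(eps)], 1)  # radius beyond the diameter
})

test_that("correlation dimension recovers known scaling exponents", {
  # uniform points on a line: C(eps) ~ eps
  withr::with_seed(22, line <- matrix(sort(runif(400)), ncol = 1))
  ccl <- correlation_sum(line, epsilons = exp(seq(log(0.005), log(0.3),
                                                  length.out = 20)))
  expect_equal(correlation_dimension(ccl)$D2, 1, tolerance = 0.1)
  # iid noise embedded at dim 2 fills the plane
  wn <- withr::with_seed(23, runif(3000))
  cc2 <- correlation_sum(delay_embed(wn, 2, 1),
                         epsilons = exp(seq(log(0.01), log(0.2),
                                            length.out = 20)), theiler = 1)
  expect_equal(correlation_dimension(cc2)$D2, 2, tolerance = 0.25)
  # noiseless sine: a limit cycle has dimension 1
  s <- sin(2 * pi * (0:2999) / 100)
  ccs <- correlation_sum(delay_embed(s, 2, 25),
                         epsilons = exp(seq(log(0.02), log(0.5),
                                            length.out = 20)), theiler = 30)
  expect_equal(correlation_dimension(ccs)$D2, 1, tolerance = 0.15)
  expect_error(correlation_dimension(ccl, fit_range = c(1e-9, 2e-9)))
})

test_that("correlation curves are invariant under affine rescaling", {
  withr::with_seed(24, states <- matrix(rnorm(400), 200, 2))
  diam <- max(apply(states, 2, function(c) diff(range(c))))
  eps_frac <- c(0.05, 0.1, 0.3, 0.6)
  c1 <- correlation_sum(states, epsilons = eps_frac * diam)
  sc <- states * 7.5 + 2
  c2 <- correlation_sum(sc, epsilons = eps_frac * diam * 7.5)
  expect_equal(c1$C, c2$C)
})

test_that("lyapunov fits recover analytic exponents", {
  # exact slope on a synthetic linear curve
  curve <- structure(list(iterations = 0:10, delta = -3 + 0.1 * (0:10),
                          n_ref = 1, algorithm = "kantz", eps = 1,
                          delta_sat = 10, fs = NULL),
                     class = "divergence_curve")
  expect_equal(lyapunov_fit(curve, fit_range = c(0, 10))$lambda_per_sample, 0.1)
  # periodic signal: no divergence
  s <- sin(2 * pi * (0:1999) / 100)
  dcs <- lyapunov_curve(delay_embed(s, 2, 25), "kantz", iterations = 40,
                        theiler = 10)
  expect_lt(abs(lyapunov_fit(dcs)$lambda_per_sample), 0.01)
  # fully chaotic logistic map: lambda = ln 2 per iterate
  lg <- logistic_series(a = 4, x0 = 0.3, n = 10000)
  dcl <- lyapunov_curve(delay_embed(lg, 1, 1), "kantz", eps = 0.005,
                        iterations = 15)
  expect_equal(lyapunov_fit(dcl)$lambda_per_sample, log(2), tolerance = 0.05)
})

test_that("Kantz and Rosenstein agree on the Lorenz exponent", {
  ps <- bench_lorenz_ps()
  diam <- max(apply(unclass(ps), 2, function(c) diff(range(c))))
  k <- lyapunov_fit(lyapunov_curve(ps, "kantz", eps = 0.003 * diam,
                                   iterations = 120, theiler = 20))
  r <- lyapunov_fit(lyapunov_curve(ps, "rosenstein", iterations = 120,
                                   theiler = 20))
  expect_gt(k$lambda_per_second, 0)
  expect_gt(r$lambda_per_second, 0)
  expect_lt(abs(k$lambda_per_second - r$lambda_per_second) /
              max(k$lambda_per_second, r$lambda_per_second), 0.10)
})

test_that("the UPO transform concentrates density at map fixed points", {
  # chaotic regime: fixed point at 1 - 1/a = 0.7449
  for (seed in 1:3) {
    lg <- logistic_series(a = 3.92, n = 100, seed = seed)
    u <- upo_transform(lg, n_transforms = 500, seed = seed)
    expect_lt(abs(u$mode - (1 - 1 / 3.92)), 0.02)
    expect_equal(sum(u$density), 1, tolerance = 1e-12)
  }
  # stable regime: fixed point at 0.5
  lg2 <- logistic_series(a = 2, x0 = 0.21, n = 100)
  expect_lt(abs(upo_transform(lg2, n_transforms = 200, seed = 1)$mode - 0.5),
            0.05)
})

test_that("UPO significance separates chaos from noise", {
  lg <- logistic_series(a = 3.92, n = 100, seed = 1)
  sig <- upo_significance(lg, n_surrogates = 60, n_transforms = 200, seed = 2)
  expect_true(sig$significant)
  expect_gt(sig$z, 2)
  wn <- withr::with_seed(25, runif(100))
  nsig <- upo_significance(wn, n_surrogates = 60, n_transforms = 200, seed = 3)
  expect_lt(abs(nsig$z), 3)
  # degenerate surrogate distribution is an error
  ens <- make_surrogates(rnorm(50), "shuffle", n = 30, seed = 1)
  expect_error(surrogate_z_test(rnorm(50), function(v) 1, ens), "variance")
})

test_that("DFA recovers the white-noise and random-walk exponents", {
  wn <- withr::with_seed(26, rnorm(5000))
  expect_equal(dfa(wn)$alpha, 0.5, tolerance = 0.05)
  rw <- cumsum(withr::with_seed(27, rnorm(5000)))
  expect_equal(dfa(rw)$alpha, 1.5, tolerance = 0.1)
  expect_error(dfa(rep(1, 1000)), "constant")
  expect_warning(dfa(wn, scales = c(16, 64, 256, 3000)), "N/4")
})
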