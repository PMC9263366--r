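test_that("delay embedding follows the backward convention", {
  ps <- delay_embed(c(1, 2, 3, 4, 5), dim = 2, tau = 1)
  expect_equal(unclass(ps)[, 1], c(1, 2, 3, 4))
  expect_equal(unclass(ps)[, 2], c(2, 3, 4, 5))
  ps1 <- delay_embed(c(3, 1, 4, 1, 5), dim = 1, tau = 3)
  expect_equal(as.vector(ps1), c(3, 1, 4, 1, 5))
  expect_equal(nrow(delay_embed(bench_lorenz()$x, 3, 8)), 9984)
  expect_error(delay_embed(1:5, dim = 3, tau = 3), "too short")
})

test_that("neighbor search is exact against a brute-force scan", {
  # collinear points
  nb <- find_neighbors(matrix(c(0, 1, 2), 3, 1), eps = 1.5)
  expect_equal(lengths(nb$neighbors), c(1, 2, 1))
  # full Theiler exclusion empties every neighborhood
  nb2 <- find_neighbors(matrix(rnorm(20), 10, 2), eps = 100, theiler = 10)
  expect_true(all(lengths(nb2$neighbors) == 0))

  withr::with_seed(9, states <- matrix(runif(400), 200, 2))
  for (norm in c("maximum", "euclidean")) {
    nb <- find_neighbors(states, eps = 0.1, norm = norm, theiler = 2)
    for (i in c(1, 17, 99, 200)) {
      ref <- which(vapply(seq_len(200), function(j) {
        abs(i - j) > 2 && brute_dist(states, i, j, norm) <= 0.1
      }, logical(1)))
      expect_identical(nb$neighbors[[i]], as.integer(ref))
    }
  }
  # k-nearest mode against ordered brute-force distances
  nbk <- find_neighbors(states, k = 5, theiler = 0)
  d1 <- vapply(2:200, function(j) brute_dist(states, 1, j), numeric(1))
  expect_equal(sort(nbk$distances[1, ]), sort(d1)[1:5])
})

test_that("auto-mutual information has the expected fixed points and null", {
  x <- withr::with_seed(4, runif(5000))
  ami <- auto_mutual_information(x, max_lag = 10)
  # AMI(0) equals the marginal entropy under the same discretization
  B <- freedman_diaconis_bins(x)
  H <- -sum((p <- tabulate(findInterval(x, seq(min(x), max(x),
        length.out = B + 1), rightmost.closed = TRUE, all.inside = TRUE),
        nbins = B) / length(x))[p > 0] * log2(p[p > 0]))
  expect_equal(ami$ami[1], H, tolerance = 1e-10)
  # iid noise: lagged AMI is indistinguishable from the shuffle null
  null_ami <- vapply(1:100, function(i) {
    xs <- withr::with_seed(1000 + i, sample(x))
    auto_mutual_information(xs, max_lag = 1)$ami[2]
  }, numeric(1))
  expect_lt(mean(ami$ami[-1]), quantile(null_ami, 0.95))
  expect_error(auto_mutual_information(rep(1, 100), max_lag = 5), "constant")
  expect_error(auto_mutual_information(x, max_lag = 4000), "max_lag")
})

test_that("false nearest neighbors identify planar and affine-invariant structure", {
  # a noiseless sine embeds in the plane: FNN ~ 0 from dim 2 upward
  s <- sin(2 * pi * (0:1999) / 100)
  fnn <- false_nearest_neighbors(s, tau = 25, dims = 1:4, theiler = 2)
  expect_gt(fnn$fnn[1], 0.05)
  expect_true(all(fnn$fnn[2:4] < 0.01))
  expect_equal(fnn$suggested_dim, 2)
  # affine rescaling leaves the fractions unchanged (generic data, where no
  # nearest-neighbor ties exist to be broken differently after rounding)
  x <- withr::with_seed(5, s + 0.05 * rnorm(2000))
  g1 <- false_nearest_neighbors(x, tau = 25, dims = 1:4, theiler = 2)
  g2 <- false_nearest_neighbors(-2.5 * x + 1, tau = 25, dims = 1:4,
                                theiler = 2)
  expect_equal(g2$fnn, g1$fnn, tolerance = 1e-12)
  # broadband stochastic signal: gradual decline, no sharp zero by dim 3
  ar <- gen_ar1(3000, phi = 0.6, seed = 8)
  fnn3 <- false_nearest_neighbors(ar, tau = 1, dims = 1:4)
  expect_true(all(fnn3$fnn[1:3] > 0.01))
  expect_error(false_nearest_neighbors(rep(2, 500), tau = 1), "constant")
})

test_that("Ragwitz optimization recovers the Markov order of an AR(1)", {
  for (seed in 1:3) {
    x <- gen_ar1(5000, phi = 0.8, seed = seed)
    rg <- ragwitz_optimize(x, dims = 1:4, taus = 1:3, k = 30)
    expect_equal(rg$dim, 1)
  }
  # the minimum RMSPE approaches the analytic error of a k-neighbor local
  # predictor, sigma * sqrt(1 + 1/k) with sigma = 1 (averaged over seeds to
  # suppress the +-2% test-set fluctuation of a single realization)
  mins <- vapply(1:5, function(s) {
    min(ragwitz_optimize(gen_ar1(5000, phi = 0.8, seed = s),
                         dims = 1:3, taus = 1, k = 100)$rmspe)
  }, numeric(1))
  expect_lt(abs(mean(mins) - sqrt(1 + 1 / 100)), 0.02)
  # a perfectly periodic series is predicted with almost no error
  s <- sin(2 * pi * (0:999) / 50)
  rgp <- ragwitz_optimize(s, dims = 2, taus = 12, k = 2, theiler = 2)
  expect_lt(min(rgp$rmspe), 0.01)
})

test_that("local-constant prediction matches its analytic limits", {
  alt <- rep(c(0, 1), 100)
  ps <- delay_embed(alt, 1, 1)
  pr <- nonlinear_predict(ps, alt, eps = 0.1, horizon = 1)
  expect_equal(pr$rmspe, 0)
  # white noise with a global neighborhood: RMSPE -> SD(x)
  wn <- withr::with_seed(11, rnorm(3000))
  psw <- delay_embed(wn, 1, 1)
  prw <- nonlinear_predict(psw, wn, eps = 100, horizon = 1)
  expect_lt(abs(prw$rmspe - sd(wn)) / sd(wn), 0.05)
})

test_that("Lorenz one-step prediction is accurate and matches brute force", {
  lo <- bench_lorenz()
  ps <- bench_lorenz_ps()
  x <- lo$x$values
  S <- unclass(ps)
  diam <- max(apply(S, 2, function(c) diff(range(c))))
  queries <- seq(1L, 8992L, by = 9L)
  pr <- nonlinear_predict(ps, x, eps = 0.05 * diam, horizon = 1,
                          queries = queries, theiler = 20)
  expect_lt(pr$rmspe, 0.05 * sd(x))
  # brute-force oracle on a few queries
  d <- 3; tau <- attr(ps, "tau"); off <- (d - 1) * tau
  for (q in queries[c(1, 500, 999)]) {
    sel <- which(vapply(seq_len(nrow(ps)), function(j) {
      abs(q - j) > 20 && j + off + 1 <= length(x) &&
        brute_dist(S, q, j) <= 0.05 * diam
    }, logical(1)))
    expect_equal(pr$pred[which(queries == q)], mean(x[sel + off + 1]))
  }
})

test_that("space-time separation curves reflect temporal structure", {
  wn <- withr::with_seed(12, runif(2000))
  psw <- delay_embed(wn, 2, 1)
  stw <- space_time_separation(psw, max_dt = 50)
  # flat for iid noise once the states share no coordinates (dt >= dim*tau)
  med <- stw$eps_q[-1, 2]
  expect_lt(diff(range(med)), 0.15 * median(med))
  # a sine's median curve oscillates with the signal period
  s <- sin(2 * pi * (0:1999) / 100)
  sts <- space_time_separation(delay_embed(s, 2, 25), max_dt = 220)
  med <- sts$eps_q[, 2]
  expect_lt(med[100], 0.1 * med[50])   # near-zero at one full period
  expect_lt(med[200], 0.1 * med[150])
  # Lorenz plateau: suggested Theiler window near the paper's choice
  stl <- space_time_separation(bench_lorenz_ps(), max_dt = 60)
  expect_true(stl$suggested_theiler >= 5 && stl$suggested_theiler <= 40)
})

test_that("embedding optimization routes to the right parameters", {
  det <- optimize_embedding(bench_lorenz()$x, "deterministic")
  expect_equal(det$dim, 3)
  expect_true(det$tau >= 7 && det$tau <= 9)
  ar <- gen_ar1(3000, phi = 0.8, seed = 2)
  sto <- optimize_embedding(ar, "stochastic", dims = 1:3, taus = 1:2, k = 30)
  expect_equal(sto$dim, 1)
  sine <- sin(2 * pi * (0:1999) / 100)
  dets <- optimize_embedding(sine, "deterministic", dims = 1:4, theiler = 2)
  expect_equal(dets$dim, 2)
})
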