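test_that("surrogate ensembles obey their conservation laws", {
  x <- gen_ar1(512, phi = 0.8, seed = 61)
  sh <- make_surrogates(x, "shuffle", n = 5, seed = 1)
  for (i in 1:5)
    expect_identical(sort(sh$realizations[i, ]), sort(x))
  ft <- make_surrogates(x, "ft", n = 5, seed = 2)
  a0 <- Mod(fft(x))
  for (i in 1:5) {
    ai <- Mod(fft(ft$realizations[i, ]))
    expect_lt(max(abs(ai - a0)) / max(a0), 1e-10)
  }
  aa <- make_surrogates(x, "aaft", n = 5, seed = 3)
  r1 <- function(v) cor(v[-1], v[-length(v)])
  for (i in 1:5) {
    expect_identical(sort(aa$realizations[i, ]), sort(x))
    expect_lt(abs(r1(aa$realizations[i, ]) - r1(x)) / abs(r1(x)), 0.05)
  }
  bs <- make_surrogates(x, "block_shuffle", n = 3, seed = 4, block_len = 32)
  for (i in 1:3)
    expect_identical(sort(bs$realizations[i, ]), sort(x))
  # fixed seed reproduces the ensemble exactly
  aa2 <- make_surrogates(x, "aaft", n = 5, seed = 3)
  expect_identical(aa$realizations, aa2$realizations)
  expect_error(make_surrogates(x, "foo"))
})

test_that("the time-reversal statistic matches hand computations", {
  expect_equal(time_reversal_statistic(c(0, 1, 3)), 4.5)
  s <- sin(2 * pi * (0:1000) / 100)  # 10 full periods of increments
  expect_lt(abs(time_reversal_statistic(s)), 1e-10)
  saw <- compound_oscillation(5, 500, 2, "sawtooth")
  expect_lt(time_reversal_statistic(saw), 0)     # fast fall, slow rise
  expect_gt(abs(time_reversal_statistic(saw)), 100 * abs(time_reversal_statistic(s)))
  expect_error(time_reversal_statistic(c(1, 2), dt = 5), "lag")
})

test_that("the surrogate Z test has the documented behavior and type-I error", {
  ens <- structure(list(realizations = rbind(c(1, 3), c(2, 2), c(0, 4)),
                        method = "shuffle", n = 3),
                   class = "surrogate_ensemble")
  # observed statistic equal to the surrogate mean -> Z = 0, nonsignificant
  z0 <- surrogate_z_test(c(1, 7), function(v) v[1], ens)
  expect_equal(z0$z, 0)
  expect_false(z0$significant)
  # applying the test to one of its own surrogates rejects at ~ alpha
  x <- gen_ar1(256, phi = 0.6, seed = 62)
  rej <- vapply(1:100, function(i) {
    surr_data <- make_surrogates(x, "aaft", n = 1, seed = i)$realizations[1, ]
    ens <- make_surrogates(x, "aaft", n = 40, seed = 5000 + i)
    surrogate_z_test(surr_data, time_reversal_statistic, ens)$significant
  }, logical(1))
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.15)
})

test_that("the Monte-Carlo permutation test is calibrated and powerful", {
  expect_equal(monte_carlo_test(rep(1, 10), rep(1, 10), n_perm = 199,
                                seed = 1)$p, 1)
  # type-I at nominal 5%: rejection rate within [2%, 9%] over 500 repeats
  rej <- vapply(1:500, function(i) {
    withr::with_seed(70000 + i, {
      a <- rnorm(50); b <- rnorm(50)
    })
    monte_carlo_test(a, b, n_perm = 199, seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  # 1-SD shift at n = 100: power above 90%
  pow <- vapply(1:100, function(i) {
    withr::with_seed(80000 + i, {
      a <- rnorm(100); b <- rnorm(100) + 1
    })
    monte_carlo_test(a, b, n_perm = 199, seed = i)$p < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.9)
  # p-values always in (0, 1] with the +1 correction
  ps <- vapply(1:20, function(i) {
    withr::with_seed(i, monte_carlo_test(rnorm(10), rnorm(10) + 3,
                                         n_perm = 100, seed = i)$p)
  }, numeric(1))
  expect_true(all(ps > 0 & ps <= 1))
  expect_gte(min(ps), 1 / 101)
  expect_error(monte_carlo_test(numeric(0), 1:5), "empty")
})

test_that("the cluster permutation test controls error and recovers effects", {
  # identical conditions: significant clusters should be rare
  fp <- vapply(1:100, function(i) {
    withr::with_seed(90000 + i, {
      a <- matrix(rnorm(8 * 40), 8, 40)
      b <- matrix(rnorm(8 * 40), 8, 40)
    })
    ct <- cluster_permutation_test(a, b, n_perm = 200, seed = i)
    ct$global_p < 0.05
  }, logical(1))
  expect_lte(mean(fp), 0.10)
  # a 20-sample 2-SD offset is recovered with >= 80% overlap
  withr::with_seed(91, {
    a <- matrix(rnorm(16 * 100), 16, 100)
    b <- matrix(rnorm(16 * 100), 16, 100)
  })
  b[, 41:60] <- b[, 41:60] + 2
  ct <- cluster_permutation_test(a, b, n_perm = 500, seed = 7)
  top <- ct$clusters[1, ]
  expect_lt(top$p, 0.05)
  overlap <- length(intersect(top$start:top$end, 41:60)) / 20
  expect_gte(overlap, 0.8)
  # a single suprathreshold sample forms a cluster of size 1
  withr::with_seed(92, {
    a1 <- matrix(rnorm(6 * 30, sd = 0.1), 6, 30)
    b1 <- matrix(rnorm(6 * 30, sd = 0.1), 6, 30)
  })
  b1[, 15] <- b1[, 15] + 5
  ct1 <- cluster_permutation_test(a1, b1, threshold = 8, n_perm = 100,
                                  seed = 8)
  expect_equal(nrow(ct1$clusters), 1)
  expect_equal(ct1$clusters$start, 15)
  expect_equal(ct1$clusters$end, 15)
  expect_error(cluster_permutation_test(matrix(0, 1, 5), matrix(0, 3, 5)),
               "trials")
})
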