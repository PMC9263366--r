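test_that("recurrence matrices have the documented structure", {
  withr::with_seed(31, ps <- matrix(runif(100), 50, 2))
  rm0 <- recurrence_matrix(ps, "epsilon", 0.2)
  expect_true(all(diag(rm0$M) == 1))
  expect_identical(rm0$M, t(rm0$M))
  # periodic signal: recurrence diagonals spaced one period apart
  s <- sin(2 * pi * (0:799) / 100)
  rms <- recurrence_matrix(delay_embed(s, 2, 25), "epsilon", 0.1, theiler = 5)
  g <- rqa_measures(rms)$gacf
  expect_gt(g[101], 0.9)   # offset = period
  expect_lt(g[51], 0.05)   # offset = half period
  # rate mode hits the requested fill rate with per-point radii
  withr::with_seed(32, u <- matrix(runif(2000), 1000, 2))
  rmr <- recurrence_matrix(u, "rate", 5)
  expect_lt(abs(mean(rmr$M) - 0.05), 0.005)
  expect_error(recurrence_matrix(u[1:10, ], "rate", 0.5), "rate")
})

test_that("joint and cross recurrence compose as documented", {
  withr::with_seed(33, a <- matrix(runif(120), 60, 2))
  j <- joint_recurrence(a, a, epsA = 0.3)
  auto <- recurrence_matrix(a, "epsilon", 0.3)
  expect_identical(j$M, auto$M)  # idempotence
  # independent noise: joint fill ~ product of individual fills
  withr::with_seed(34, b <- matrix(runif(800), 400, 2))
  withr::with_seed(35, c2 <- matrix(runif(800), 400, 2))
  jb <- joint_recurrence(b, c2, epsA = 0.25, epsB = 0.25)
  fb <- mean(recurrence_matrix(b, "epsilon", 0.25)$M)
  fc <- mean(recurrence_matrix(c2, "epsilon", 0.25)$M)
  expect_equal(mean(jb$M), fb * fc, tolerance = 0.1)
  # cross recurrence of a series with itself has a unit main diagonal
  cr <- cross_recurrence(b, b, eps = 0.01)
  expect_true(all(diag(cr$M) == 1))
  expect_error(cross_recurrence(b, matrix(0, 10, 3), eps = 1), "dimension")
})

test_that("RQA measures separate periodic, constant and stochastic signals", {
  s <- sin(2 * pi * (0:599) / 50)
  rqs <- rqa_measures(recurrence_matrix(delay_embed(s, 2, 12), "epsilon",
                                        0.05, theiler = 3))
  expect_gte(rqs$det, 0.99)
  expect_lt(rqs$rpde, 0.2)
  const <- recurrence_matrix(matrix(1, 50, 1), "epsilon", 0.5)
  rqc <- rqa_measures(const)
  expect_equal(rqc$recurrence_rate, 1)
  expect_equal(rqc$lam, 1)
  wn <- withr::with_seed(36, runif(500))
  rqw <- rqa_measures(recurrence_matrix(delay_embed(wn, 2, 1), "epsilon",
                                        0.05, theiler = 3))
  expect_lt(rqw$det, 0.5)
  empty <- recurrence_matrix(matrix(c(0, 10, 20), 3, 1), "epsilon", 1,
                             theiler = 2)
  expect_error(rqa_measures(empty), "empty")
})

test_that("recurrence-time extraction equals vertical zero-run counting", {
  # oracle: explicit recurrence matrix, forward column scan
  gap_oracle <- function(M, theiler, Tmin, Tmax) {
    n <- nrow(M)
    gaps <- integer(0)
    for (i in seq_len(n)) {
      start <- i + theiler + 1L
      if (start > n) next
      col <- c(1L, M[start:n, i])
      r <- rle(col)
      k <- length(r$values)
      if (k >= 3)
        for (q in 2:(k - 1))
          if (r$values[q] == 0 && r$values[q - 1] == 1 && r$values[q + 1] == 1)
            gaps <- c(gaps, r$lengths[q])
    }
    tabulate(gaps[gaps >= Tmin & gaps <= Tmax] - Tmin + 1L,
             nbins = Tmax - Tmin + 1L)
  }
  for (seed in c(41, 42)) {
    wn <- withr::with_seed(seed, runif(300))
    ps <- delay_embed(wn, 2, 1)
    eps <- 0.15
    rt <- recurrence_times(ps, eps, Tmin = 1, Tmax = 60, theiler = 2)
    M <- recurrence_matrix(ps, "epsilon", eps, theiler = 2)$M
    diag(M) <- 1L  # reference cell is recurrent by definition
    expect_equal(rt$R, gap_oracle(M, 2, 1, 60))
  }
})

test_that("recurrence-time densities normalize and locate periods", {
  s <- sin(2 * pi * (0:1999) / 80)
  rt <- recurrence_times(delay_embed(s, 2, 20), eps = 0.1, Tmax = 200,
                         theiler = 5)
  expect_equal(sum(rt$P), 1)
  expect_equal(rt$T[which.max(rt$P)], 80, tolerance = 2)
  # no recurrences at all -> flagged empty
  line <- matrix(seq(0, 100, length.out = 50), ncol = 1)
  rte <- recurrence_times(line, eps = 0.1, Tmax = 20)
  expect_true(rte$empty)
})

test_that("recurrence amplitudes report waveform amplitude and scale linearly", {
  # 20 Hz sinusoid of amplitude 2 sampled at 1000 Hz (period 50 samples);
  # quarter-period delay makes the orbit a circle of radius 2
  s2 <- compound_oscillation(20, 1000, 2, "sine", amplitude = 2)
  ps <- delay_embed(s2, 2, 12)
  rt <- recurrence_amplitude(ps, eps = 0.2, Tmax = 100, theiler = 5)
  peak <- which.max(rt$P)
  expect_equal(rt$T[peak], 50, tolerance = 2)
  expect_equal(rt$amplitude[peak], 2, tolerance = 0.2)
  # doubling the signal amplitude doubles the reported amplitude
  s4 <- compound_oscillation(20, 1000, 2, "sine", amplitude = 4)
  rt4 <- recurrence_amplitude(delay_embed(s4, 2, 12), eps = 0.4, Tmax = 100,
                              theiler = 5)
  expect_equal(rt4$amplitude[which.max(rt4$P)],
               2 * rt$amplitude[peak], tolerance = 0.1)
  # constant signal: no excursion ever leaves the neighborhood
  rtc <- recurrence_times(matrix(1, 40, 1), eps = 0.5, Tmax = 10)
  expect_true(all(rtc$weighted_amplitude == 0))
})

test_that("SREPS columns are probability distributions with the documented shape", {
  sig <- compound_oscillation(3, 100, 50, "sine", noise_frac = 0.08, seed = 7)
  sp <- sreps(sig, dim = 2, tau = 8, Tmax = 100)
  nonempty <- sp$totals > 0
  expect_true(all(abs(colSums(sp$P[, nonempty]) - 1) < 1e-12))
  expect_equal(colSums(sp$counts), sp$totals)
  # band drifts toward smaller T as the radius grows
  fp <- fundamental_period(sp)
  band <- fp$band[!is.na(fp$band)]
  expect_true(all(diff(band) <= 0))
  expect_equal(fp$period, 33, tolerance = 2)
  # very large radii shift mass toward small T
  meanT <- function(e) sum(sp$T * sp$P[, e])
  expect_lt(meanT(100), meanT(fp$scale))
})

test_that("TRAS tracks a stationary band and counts windows correctly", {
  s <- compound_oscillation(10, 500, 8, "sine", noise_frac = 0.02, seed = 8)
  tr <- tras(s, dim = 2, tau = 12, eps_sd_pct = 20, window_len = 500,
             Tmax = 100)
  expect_equal(length(tr$scale), floor((4000 - 500) / 250) + 1)
  modal <- tr$T[apply(tr$P, 2, which.max)]
  expect_true(all(abs(modal - 50) <= 3))  # 10 Hz @ 500 Hz = 50 samples
  expect_error(tras(s, dim = 5, tau = 100, window_len = 300), "window")
})

test_that("TRAS of the compound signal shows one band and no harmonics", {
  sig <- compound_oscillation(33, 1000, 5, c("sine", "sawtooth", "square"))
  tr <- tras(sig, dim = 2, tau = 8, eps_sd_pct = 20, window_len = 1100,
             Tmax = 120)
  f0 <- 1000 / 33
  fund <- colSums(tr$P[abs(tr$T - f0) <= 8, ])
  harm <- colSums(tr$P[abs(tr$T - f0 / 2) <= 3, ])
  expect_true(all(fund > 0.5))
  expect_true(all(harm < 0.05))
})
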