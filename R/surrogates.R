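#' Surrogate-data ensembles
#'
#' Generates `n` randomized realizations of a series that preserve selected
#' linear properties, for use as the null ensemble of nonlinearity tests:
#' \describe{
#'   \item{`shuffle`}{random permutation — preserves the value multiset
#'     exactly, destroys all temporal structure.}
#'   \item{`block_shuffle`}{permutes contiguous blocks (default block length
#'     = the autocorrelation time) — preserves short-range structure within
#'     blocks.}
#'   \item{`ft`}{phase randomization — preserves the amplitude spectrum
#'     exactly (Hermitian-symmetric random phases), hence the linear
#'     autocorrelation.}
#'   \item{`aaft`}{amplitude-adjusted phase randomization — after phase
#'     randomization, iteratively (i) rank-remaps the values back onto the
#'     original multiset and (ii) restores the original amplitude spectrum,
#'     until the relative spectral discrepancy changes by less than `tol`
#'     (or `n_iterations` is reached); the iteration ends on the rank step
#'     so the value distribution is preserved exactly.}
#' }
#'
#' @param ts `nlts` or numeric vector.
#' @param method surrogate algorithm.
#' @param n ensemble size (default 100).
#' @param seed integer seed.
#' @param block_len block length for `block_shuffle` (`NULL`: the
#'   autocorrelation time).
#' @param n_iterations maximum refinement iterations for `aaft`.
#' @param tol relative spectral-discrepancy change below which the `aaft`
#'   iteration stops.
#' @return A `surrogate_ensemble` list with `realizations` (`n x N`
#'   matrix), `method` and parameters.
#' @export
make_surrogates <- function(ts, method = c("aaft", "ft", "shuffle",
                                           "block_shuffle"),
                            n = 100, seed = NULL, block_len = NULL,
                            n_iterations = 100, tol = 1e-4) {
  method <- match.arg(method)
  x <- ts_values(ts)
  N <- length(x)
  stopifnot(n >= 1)
  if (method == "block_shuffle" && is.null(block_len))
    block_len <- autocorrelation_time(x)
  real <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      switch(method,
        shuffle = x[sample.int(N)],
        block_shuffle = block_shuffle_one(x, block_len),
        ft = ft_surrogate(x),
        aaft = aaft_surrogate(x, n_iterations, tol))
    }, numeric(N)))
  })
  structure(list(realizations = real, method = method, n = n, seed = seed,
                 block_len = block_len, n_iterations = n_iterations),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d %s surrogates of a %d-sample series\n",
              x$n, x$method, ncol(x$realizations)))
  invisible(x)
}

block_shuffle_one <- function(x, block_len) {
  N <- length(x)
  block_len <- max(1L, as.integer(block_len))
  nb <- ceiling(N / block_len)
  idx <- unlist(lapply(sample.int(nb), function(b) {
    seq((b - 1L) * block_len + 1L, min(b * block_len, N))
  }))
  x[idx]
}

# Hermitian-symmetric random phases; DC (and Nyquist, if present) kept real.
random_phases <- function(N) {
  ph <- numeric(N)
  half <- floor((N - 1) / 2)
  if (half > 0) {
    r <- runif(half, 0, 2 * pi)
    ph[2:(half + 1)] <- r
    ph[N:(N - half + 1)] <- -r
  }
  ph
}

ft_surrogate <- function(x) {
  N <- length(x)
  amp <- Mod(fft(x))
  Re(fft(amp * exp(1i * random_phases(N)), inverse = TRUE)) / N
}

aaft_surrogate <- function(x, n_iterations, tol) {
  N <- length(x)
  xs <- sort(x)
  amp <- Mod(fft(x))
  s <- ft_surrogate(x)
  prev_disc <- Inf
  for (it in seq_len(n_iterations)) {
    # (4) rank-remap onto the original value multiset
    s <- xs[rank(s, ties.method = "first")]
    # (5)-(7) restore the original amplitude spectrum, keep surrogate phases
    f <- fft(s)
    disc <- sqrt(sum((Mod(f) - amp)^2)) / sqrt(sum(amp^2))
    if (is.finite(prev_disc) && abs(prev_disc - disc) < tol) break
    prev_disc <- disc
    s <- Re(fft(amp * exp(1i * Arg(f)), inverse = TRUE)) / N
  }
  # end on the rank step: value distribution preserved exactly
  xs[rank(s, ties.method = "first")]
}

#' Time-reversal asymmetry statistic
#'
#' \deqn{Q(\Delta t) = \langle (x_t - x_{t-\Delta t})^3 \rangle} — the mean
#' cubed backward difference, a sensitive marker of temporal asymmetry:
#' linear Gaussian processes are statistically time-reversible (`Q ~ 0`),
#' while signals with asymmetric rise/fall (e.g. a sawtooth) give strongly
#' signed values.
#'
#' @param ts `nlts` or numeric vector.
#' @param dt lag in samples (default 1).
#' @return The scalar statistic.
#' @examples
#' time_reversal_statistic(c(0, 1, 3))  # ((1)^3 + (2)^3) / 2 = 4.5
#' @export
time_reversal_statistic <- function(ts, dt = 1) {
  x <- ts_values(ts)
  dt <- as.integer(dt)
  stopifnot(dt >= 1)
  if (length(x) <= dt) stop("series no longer than the lag")
  mean(diff(x, lag = dt)^3)
}

#' Surrogate Z test
#'
#' Compares an observed statistic against its distribution over a surrogate
#' ensemble: `Z = (observed - mean(surrogates)) / sd(surrogates)`, with a
#' two-sided normal p-value. The null (that the statistic is compatible
#' with the surrogate-preserved properties, e.g. linearity) is rejected at
#' level `alpha` when `|Z|` exceeds the corresponding normal quantile
#' (1.96 at 5%).
#'
#' @param ts `nlts` or numeric vector.
#' @param statistic_fn function mapping a numeric vector to a scalar.
#' @param ensemble a `surrogate_ensemble` from [make_surrogates()].
#' @param alpha significance level.
#' @return A `surrogate_test` list with `observed`, `surrogates`, `z`, `p`,
#'   `significant`.
#' @export
surrogate_z_test <- function(ts, statistic_fn, ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  x <- ts_values(ts)
  obs <- statistic_fn(x)
  surr <- apply(ensemble$realizations, 1, statistic_fn)
  s <- sd(surr)
  if (s == 0) stop("zero surrogate variance: Z undefined")
  z <- (obs - mean(surr)) / s
  structure(list(observed = obs, surrogates = surr, z = z,
                 p = 2 * pnorm(-abs(z)), alpha = alpha,
                 significant = abs(z) > qnorm(1 - alpha / 2),
                 statistic = deparse(substitute(statistic_fn))[1]),
            class = "surrogate_test")
}

#' Time-reversal nonlinearity test
#'
#' Convenience pipeline: computes the time-reversal asymmetry statistic of
#' the series and of a surrogate ensemble and returns the surrogate Z test.
#'
#' @param ts `nlts` or numeric vector.
#' @param method surrogate method (default `"aaft"`).
#' @param n number of surrogates.
#' @param dt lag of the statistic.
#' @param seed integer seed.
#' @param alpha significance level.
#' @return A `surrogate_test`.
#' @export
test_nonlinearity <- function(ts, method = "aaft", n = 100, dt = 1,
                              seed = NULL, alpha = 0.05) {
  ens <- make_surrogates(ts, method = method, n = n, seed = seed)
  out <- surrogate_z_test(ts, function(v) time_reversal_statistic(v, dt = dt),
                          ens, alpha = alpha)
  out$statistic <- sprintf("time-reversal Q(dt = %d)", dt)
  out
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf("<surrogate_test> %s: observed %.4g vs %d surrogates; Z = %.3f, p = %.4g (%ssignificant at %g%%)\n",
              x$statistic, x$observed, length(x$surrogates), x$z, x$p,
              if (x$significant) "" else "not ", 100 * x$alpha))
  invisible(x)
}

#' Monte-Carlo permutation test for two samples
#'
#' Two-sided permutation test of a scalar two-sample statistic (default:
#' difference of means) by random relabeling. The p-value carries the +1
#' correction, `p = (1 + #{|stat_perm| >= |stat_obs|}) / (n_perm + 1)`, so
#' it is never exactly zero.
#'
#' @param a,b numeric samples.
#' @param statistic function `(a, b) -> scalar`; default mean difference.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param alpha significance level.
#' @return A `permutation_test` list with `observed`, `p`, `significant`.
#' @export
monte_carlo_test <- function(a, b, statistic = NULL, n_perm = 1000,
                             seed = NULL, alpha = 0.05) {
  a <- ts_values(a)
  b <- ts_values(b)
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  stopifnot(n_perm >= 100)
  if (is.null(statistic)) statistic <- function(a, b) mean(a) - mean(b)
  obs <- statistic(a, b)
  pool <- c(a, b)
  na <- length(a)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    statistic(pool[idx], pool[-idx])
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, permuted = perm, p = p, n_perm = n_perm,
                 alpha = alpha, significant = p < alpha,
                 kind = "monte_carlo"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> (%s) observed %.4g, p = %.4g over %d permutations (%ssignificant at %g%%)\n",
              x$kind, x$observed, x$p, x$n_perm,
              if (x$significant) "" else "not ", 100 * x$alpha))
  invisible(x)
}

#' Cluster-based permutation test for trialwise series
#'
#' Compares two conditions given as trials-by-samples matrices. A pointwise
#' two-sample t statistic is computed per sample; samples whose |t| exceeds
#' a threshold (by default the 97.5th percentile of the pointwise
#' permutation distribution of |t|) form contiguous clusters whose mass is
#' the sum of |t| inside; each observed cluster's mass is compared with the
#' permutation null distribution of the maximum cluster mass, controlling
#' the familywise error over samples.
#'
#' @param condA,condB numeric matrices (trials x samples, equal sample
#'   count, >= 2 trials each).
#' @param threshold fixed |t| threshold, or `NULL` for the permutation
#'   quantile default.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param alpha cluster-level significance level.
#' @return A `cluster_test` list: `clusters` (data frame with `start`,
#'   `end`, `mass`, `p`), the pointwise `t` values, `threshold`.
#' @export
cluster_permutation_test <- function(condA, condB, threshold = NULL,
                                     n_perm = 500, seed = NULL,
                                     alpha = 0.05) {
  condA <- as.matrix(condA)
  condB <- as.matrix(condB)
  if (ncol(condA) != ncol(condB)) stop("conditions differ in sample count")
  if (nrow(condA) < 2 || nrow(condB) < 2) stop("need >= 2 trials per condition")
  ns <- ncol(condA)
  na <- nrow(condA)
  all_tr <- rbind(condA, condB)
  nt <- nrow(all_tr)
  tstat <- function(lab) {
    A <- all_tr[lab, , drop = FALSE]
    B <- all_tr[!lab, , drop = FALSE]
    ma <- colMeans(A); mb <- colMeans(B)
    va <- apply(A, 2, var) / nrow(A)
    vb <- apply(B, 2, var) / nrow(B)
    (ma - mb) / sqrt(pmax(va + vb, .Machine$double.eps))
  }
  lab_obs <- c(rep(TRUE, na), rep(FALSE, nt - na))
  t_obs <- tstat(lab_obs)
  with_seed(seed, {
    perm_t <- matrix(0, n_perm, ns)
    for (i in seq_len(n_perm)) {
      lab <- logical(nt)
      lab[sample.int(nt, na)] <- TRUE
      perm_t[i, ] <- tstat(lab)
    }
    if (is.null(threshold)) threshold <- quantile(abs(perm_t), 0.975)
    cluster_masses <- function(tv) {
      supra <- abs(tv) > threshold
      if (!any(supra)) return(NULL)
      r <- rle(supra)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      data.frame(start = starts[keep], end = ends[keep],
                 mass = vapply(keep, function(k) {
                   sum(abs(tv[starts[k]:ends[k]]))
                 }, numeric(1)))
    }
    obs_cl <- cluster_masses(t_obs)
    null_max <- vapply(seq_len(n_perm), function(i) {
      cl <- cluster_masses(perm_t[i, ])
      if (is.null(cl)) 0 else max(cl$mass)
    }, numeric(1))
    if (is.null(obs_cl)) {
      clusters <- data.frame(start = integer(0), end = integer(0),
                             mass = numeric(0), p = numeric(0))
      global_p <- 1
    } else {
      obs_cl$p <- vapply(obs_cl$mass, function(m) {
        (1 + sum(null_max >= m)) / (n_perm + 1)
      }, numeric(1))
      clusters <- obs_cl[order(obs_cl$p), ]
      global_p <- min(clusters$p)
    }
    structure(list(clusters = clusters, t = t_obs, threshold = threshold,
                   global_p = global_p, n_perm = n_perm, alpha = alpha),
              class = "cluster_test")
  })
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> |t| threshold %.3f, %d permutations; %d cluster(s), global p = %.4g\n",
              x$threshold, x$n_perm, nrow(x$clusters), x$global_p))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
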