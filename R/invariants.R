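#' Grassberger-Procaccia correlation sum
#'
#' Fraction of admissible state pairs closer than each radius:
#' \deqn{C(\varepsilon) = \frac{2}{N_p} \sum_{i<j,\ |i-j|>w}
#'   \Theta(\varepsilon - \|x_i - x_j\|)}
#' normalized by the number of Theiler-admissible pairs so that
#' `C == 1` once the radius reaches the attractor diameter.
#'
#' @param ps `phase_space` or state matrix.
#' @param epsilons radii in data units; default 40 log-spaced values over
#'   1--100% of the attractor diameter.
#' @param theiler Theiler window `w`.
#' @param norm distance norm.
#' @return A `correlation_curve` list with `epsilons`, `C`, `counts`,
#'   `n_pairs` and the embedding dimension of `ps`.
#' @export
correlation_sum <- function(ps, epsilons = NULL, theiler = 0,
                            norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  states <- ps_states(ps)
  theiler <- as.integer(theiler)
  if (is.null(epsilons)) {
    diam <- attractor_diameter(states, norm)
    epsilons <- exp(seq(log(0.01 * diam), log(diam), length.out = 40))
  }
  epsilons <- sort(as.numeric(epsilons))
  r <- corr_sum_cpp(states, epsilons, theiler, norm == "maximum")
  if (r$npairs < 2) stop("fewer than 2 Theiler-admissible state pairs")
  structure(list(epsilons = epsilons, C = r$counts / r$npairs,
                 counts = r$counts, n_pairs = r$npairs,
                 dim = attr(ps, "dim_embed"), theiler = theiler, norm = norm),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d radii in [%.4g, %.4g], %g admissible pairs (theiler %d)\n",
              length(x$epsilons), min(x$epsilons), max(x$epsilons),
              x$n_pairs, x$theiler))
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  ok <- x$C > 0
  graphics::plot(log10(x$epsilons[ok]), log10(x$C[ok]), type = "b",
                 xlab = "log10 eps", ylab = "log10 C(eps)", ...)
  invisible(x)
}

#' Correlation dimension from a correlation curve
#'
#' Least-squares slope of `log C(eps)` against `log eps` within a fit range.
#' When no range is given, [propose_fit_range()] picks the longest interval
#' of stable local slope, skipping radii whose pair counts are too small to
#' be reliable.
#'
#' @param curve a `correlation_curve`.
#' @param fit_range length-2 numeric: radius interval (data units) to fit
#'   over, or `NULL` for automatic selection.
#' @param min_pairs radii with fewer pairs than this are excluded from
#'   automatic range selection.
#' @return List with `D2` (the slope), `fit_range` and the points used.
#' @export
correlation_dimension <- function(curve, fit_range = NULL, min_pairs = 10) {
  stopifnot(inherits(curve, "correlation_curve"))
  ok <- curve$C > 0 & curve$counts >= if (is.null(fit_range)) min_pairs else 1
  le <- log(curve$epsilons[ok])
  lc <- log(curve$C[ok])
  if (is.null(fit_range)) {
    pr <- propose_fit_range(le, lc)
    sel <- le >= pr[1] & le <= pr[2]
  } else {
    sel <- curve$epsilons[ok] >= fit_range[1] & curve$epsilons[ok] <= fit_range[2]
  }
  if (sum(sel) < 3) stop("fewer than 3 usable points in the fit range")
  fit <- lm(lc[sel] ~ le[sel])
  list(D2 = unname(coef(fit)[2]),
       fit_range = range(curve$epsilons[ok][sel]),
       log_eps = le[sel], log_C = lc[sel])
}

#' Propose a scaling-region fit range
#'
#' Scans local slopes of `y` against `x` over a sliding window and returns
#' the x-interval of the longest contiguous run whose local slopes stay
#' within a relative tolerance of the run's median slope. Formalizes the
#' usual by-eye choice of the linear scaling region in log-log and
#' divergence plots.
#'
#' @param x,y numeric vectors (already on the scale to be fitted).
#' @param window sliding-window width in points (>= 2).
#' @param tol relative slope tolerance (default 0.15).
#' @return Length-2 numeric: the x-range of the selected run.
#' @export
propose_fit_range <- function(x, y, window = 5, tol = 0.15) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  window <- max(2L, as.integer(window))
  if (n < window + 1L) return(range(x))
  ns <- n - window + 1L
  slopes <- vapply(seq_len(ns), function(i) {
    xi <- x[i:(i + window - 1L)]
    yi <- y[i:(i + window - 1L)]
    unname(coef(lm(yi ~ xi))[2])
  }, numeric(1))
  best <- c(1L, 1L)  # start, length
  i <- 1L
  while (i <= ns) {
    j <- i
    repeat {
      med <- median(slopes[i:j])
      if (any(abs(slopes[i:j] - med) > tol * max(abs(med), 1e-12))) break
      if (j - i + 1L > best[2]) best <- c(i, j - i + 1L)
      if (j == ns) break
      j <- j + 1L
    }
    i <- i + 1L
  }
  i0 <- best[1]
  i1 <- best[1] + best[2] - 1L + window - 1L
  c(x[i0], x[min(i1, n)])
}

#' Neighbor-divergence curve for the largest Lyapunov exponent
#'
#' Tracks how the (log) distance between initially close states grows with
#' time. The Kantz variant averages, per reference state, the log of the
#' mean distance to all neighbors initially within `eps`; the Rosenstein
#' variant uses only the single nearest neighbor. A positive slope of the
#' curve over its linear region estimates the largest Lyapunov exponent.
#'
#' @param ps `phase_space`.
#' @param algorithm `"kantz"` or `"rosenstein"`.
#' @param eps neighborhood radius for Kantz (default 5% of the attractor
#'   diameter).
#' @param iterations number of time steps tracked (default 10).
#' @param theiler Theiler window.
#' @param norm distance norm (neighbor search).
#' @param scalar_dist measure the propagated distance on the newest scalar
#'   coordinate only (default), which keeps the divergence from being
#'   smeared over the `(dim-1)*tau`-sample embedding window; `FALSE` uses
#'   the full state distance.
#' @return A `divergence_curve` list with `iterations` (0..`iterations`),
#'   `delta` (mean log distances), `n_ref` and `fs`.
#' @export
lyapunov_curve <- function(ps, algorithm = c("kantz", "rosenstein"),
                           eps = NULL, iterations = 10, theiler = 0,
                           norm = c("maximum", "euclidean"),
                           scalar_dist = TRUE) {
  algorithm <- match.arg(algorithm)
  norm <- match.arg(norm)
  states <- ps_states(ps)
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1, nrow(states) > iterations + 1)
  if (algorithm == "kantz" && is.null(eps))
    eps <- 0.05 * attractor_diameter(states, norm)
  r <- lyap_cpp(states, algorithm == "kantz",
                if (is.null(eps)) 0 else eps, iterations,
                as.integer(theiler), norm == "maximum", isTRUE(scalar_dist))
  if (r$n_ref == 0) stop("all reference points had empty neighborhoods")
  # saturation level: log mean distance of temporally unrelated state pairs
  n <- nrow(states)
  idx <- round(seq(1, n, length.out = min(n, 250L)))
  sub <- states[idx, , drop = FALSE]
  if (isTRUE(scalar_dist)) {
    v <- sub[, ncol(sub)]
    dd <- abs(outer(v, v, `-`))
  } else {
    dd <- state_dist_matrix(sub, sub, norm)
  }
  delta_sat <- log(mean(dd[upper.tri(dd)]))
  structure(list(iterations = 0:iterations, delta = r$delta,
                 n_ref = r$n_ref, algorithm = algorithm, eps = eps,
                 delta_sat = delta_sat, fs = attr(ps, "fs")),
            class = "divergence_curve")
}

#' @export
print.divergence_curve <- function(x, ...) {
  cat(sprintf("<divergence_curve> %s algorithm, %d reference states, iterations 0..%d\n",
              x$algorithm, x$n_ref, max(x$iterations)))
  invisible(x)
}

#' @export
plot.divergence_curve <- function(x, ...) {
  graphics::plot(x$iterations, x$delta, type = "b", xlab = "iterations (samples)",
                 ylab = "mean log distance", ...)
  invisible(x)
}

#' Fit the largest Lyapunov exponent from a divergence curve
#'
#' Straight-line fit of the mean log distance against iteration count. The
#' slope per sample is always reported; when the phase space carried a
#' sampling rate the natural-time exponent per second (slope times `fs`) is
#' reported as well.
#'
#' The default fit range is chosen from the curve's structure: iterations
#' where the mean log distance comes within `sat_margin` (log units) of the
#' saturation level (the log mean distance of unrelated state pairs) are
#' excluded, and the fit covers the later half of what remains. The early
#' half is excluded because neighbor pairs first have to align with the
#' locally most expanding direction before their separation grows at the
#' largest exponent; that alignment transient inflates the initial slope.
#' Fitting a flat saturated stretch instead returns a spurious exponent
#' near zero, which is why saturated iterations are never included by
#' default.
#'
#' @param curve a `divergence_curve`.
#' @param fit_range length-2 iteration interval, or `NULL` for the
#'   automatic choice above.
#' @param sat_margin log-distance margin kept below saturation (default
#'   0.5).
#' @return List with `lambda_per_sample`, `lambda_per_second` (or `NA`) and
#'   `fit_range`.
#' @export
lyapunov_fit <- function(curve, fit_range = NULL, sat_margin = 0.5) {
  stopifnot(inherits(curve, "divergence_curve"))
  it <- curve$iterations
  de <- curve$delta
  ok <- is.finite(de)
  if (is.null(fit_range)) {
    unsat <- ok & de <= curve$delta_sat - sat_margin
    t_end <- if (any(unsat)) max(it[unsat]) else max(it[ok])
    if (t_end < 4) {
      fit_range <- propose_fit_range(it[ok], de[ok], window = 4)
    } else {
      fit_range <- c(ceiling(t_end / 2), t_end)
    }
  }
  sel <- ok & it >= fit_range[1] & it <= fit_range[2]
  if (sum(sel) < 2) stop("fit range selects fewer than 2 points")
  fit <- lm(de[sel] ~ it[sel])
  lam <- unname(coef(fit)[2])
  list(lambda_per_sample = lam,
       lambda_per_second = if (is.null(curve$fs)) NA_real_ else lam * curve$fs,
       fit_range = fit_range)
}

#' Period-one unstable-periodic-orbit transform
#'
#' Detects period-one orbits of a map from its two-dimensional return
#' representation `(x_n, x_{n+1})`. For every point, the local map slope
#' `s_n` is estimated by least squares over its `k` nearest neighbors'
#' successor pairs, perturbed per repetition by `r (x_{n+1} - x_n)` with
#' `r ~ U[-kappa, kappa]`, and the point is sent to the fixed point of the
#' local linearization, `x* = (x_{n+1} - s_n x_n) / (1 - s_n)`. True fixed
#' points are insensitive to the perturbation (there `x_{n+1} = x_n`) and
#' accumulate across repetitions, while unrelated points disperse. The
#' accumulated transformed values are histogrammed along the phase-space
#' diagonal.
#'
#' @param ts `nlts` or numeric vector (iterates of a map).
#' @param n_transforms number of randomized repetitions (default 500).
#' @param kappa slope-perturbation scale, units 1/data (default
#'   `0.5 / SD(x)`). The scale must be large enough that the randomized
#'   repetitions disperse points far from the diagonal; points near the
#'   diagonal (`x_{n+1} = x_n`) are insensitive to it by construction.
#' @param k neighbor count for the local least-squares slope.
#' @param nbins histogram bin count over the data range.
#' @param seed integer seed for the perturbations.
#' @return A `upo_result` list with `breaks`, `mids`, `density` (normalized
#'   to unit mass), `mode` (bin midpoint of the highest density) and
#'   bookkeeping fields.
#' @export
upo_transform <- function(ts, n_transforms = 500, kappa = NULL, k = 10,
                          nbins = 100, seed = NULL) {
  x <- ts_values(ts)
  n <- length(x) - 1L
  if (n < k + 2L) stop("series too short for the UPO transform")
  if (is.null(kappa)) kappa <- 0.5 / sd(x)
  a <- x[seq_len(n)]        # x_n
  b <- x[seq_len(n) + 1L]   # x_{n+1}
  # k nearest neighbors of each point in the (x_n, x_{n+1}) plane
  nb <- nn_knn_cpp(cbind(a, b), as.integer(k), 0L, TRUE)$idx
  slope <- numeric(n)
  for (i in seq_len(n)) {
    j <- nb[i, ]
    j <- j[!is.na(j)]
    aj <- a[j]; bj <- b[j]
    va <- sum((aj - mean(aj))^2)
    slope[i] <- if (va == 0) NA_real_ else sum((aj - mean(aj)) * (bj - mean(bj))) / va
  }
  lo <- min(x); hi <- max(x)
  breaks <- seq(lo, hi, length.out = nbins + 1L)
  accum <- numeric(nbins)
  tol <- 1e-8
  with_seed(seed, {
    for (rep in seq_len(n_transforms)) {
      r <- runif(n, -kappa, kappa)
      s <- slope + r * (b - a)
      ok <- is.finite(s) & abs(1 - s) > tol
      xs <- (b[ok] - s[ok] * a[ok]) / (1 - s[ok])
      xs <- xs[xs >= lo & xs <= hi]
      if (length(xs))
        accum <- accum + tabulate(findInterval(xs, breaks,
                                               rightmost.closed = TRUE,
                                               all.inside = TRUE),
                                  nbins = nbins)
    }
  })
  if (sum(accum) == 0) stop("no transformed points fell inside the data range")
  dens <- accum / sum(accum)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(breaks = breaks, mids = mids, density = dens,
                 mode = mids[which.max(dens)], n_transforms = n_transforms,
                 kappa = kappa, k = k),
            class = "upo_result")
}

#' @export
print.upo_result <- function(x, ...) {
  cat(sprintf("<upo_result> %d transform repetitions; density mode on the diagonal at %.4g\n",
              x$n_transforms, x$mode))
  invisible(x)
}

#' @export
plot.upo_result <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h", xlab = "diagonal coordinate",
                 ylab = "density", ...)
  graphics::abline(v = x$mode, lty = 2)
  invisible(x)
}

#' Surrogate significance of a UPO density peak
#'
#' Compares the peak height of the observed diagonal density from
#' [upo_transform()] against the peak heights obtained from surrogate
#' series, as a standard score. A large positive Z indicates that the mode
#' concentrates far more mass than surrogate data (which share the value
#' distribution and linear spectrum) can produce.
#'
#' @param ts `nlts` or numeric vector.
#' @param n_surrogates number of surrogate series (>= 1).
#' @param method surrogate generation method, see [make_surrogates()].
#' @param n_transforms,kappa,k,nbins passed to [upo_transform()].
#' @param alpha significance level for the two-sided decision.
#' @param seed integer seed (drives both surrogates and transforms).
#' @return A `surrogate_test` list with the observed peak, surrogate peaks,
#'   `z`, `p` and `significant`.
#' @export
upo_significance <- function(ts, n_surrogates = 100, method = "aaft",
                             n_transforms = 500, kappa = NULL, k = 10,
                             nbins = 100, alpha = 0.05, seed = NULL) {
  stopifnot(n_surrogates >= 1)
  x <- ts_values(ts)
  obs <- max(upo_transform(x, n_transforms = n_transforms, kappa = kappa,
                           k = k, nbins = nbins, seed = seed)$density)
  ens <- make_surrogates(x, method = method, n = n_surrogates, seed = seed)
  surr <- vapply(seq_len(n_surrogates), function(i) {
    max(upo_transform(ens$realizations[i, ], n_transforms = n_transforms,
                      kappa = kappa, k = k, nbins = nbins, seed = seed)$density)
  }, numeric(1))
  if (sd(surr) == 0) stop("degenerate surrogate peak distribution (zero variance)")
  z <- (obs - mean(surr)) / sd(surr)
  p <- 2 * pnorm(-abs(z))
  structure(list(observed = obs, surrogates = surr, z = z, p = p,
                 alpha = alpha, significant = abs(z) > qnorm(1 - alpha / 2),
                 statistic = "UPO diagonal density peak"),
            class = "surrogate_test")
}

#' Detrended fluctuation analysis
#'
#' Integrates the centered series, detrends it piecewise with polynomials of
#' the given order over non-overlapping windows of each scale, and fits the
#' log-log slope of the RMS fluctuation against scale. White noise gives
#' `alpha ~ 0.5`, a random walk `alpha ~ 1.5`, long-range-correlated signals
#' values in between or above.
#'
#' @param ts `nlts` or numeric vector (non-constant).
#' @param scales integer window sizes; default 12 log-spaced scales between
#'   `order + 2` (at least 4) and `N/4`. Scales above `N/4` are dropped with
#'   a warning.
#' @param order detrending polynomial order (default 1, linear).
#' @return A `dfa_result` list with `scales`, `F` (RMS fluctuations) and
#'   `alpha` (log-log slope).
#' @export
dfa <- function(ts, scales = NULL, order = 1) {
  x <- ts_values(ts)
  n <- length(x)
  if (sd(x) == 0) stop("constant series: zero fluctuations at every scale")
  order <- as.integer(order)
  if (is.null(scales)) {
    lo <- max(4L, order + 2L)
    scales <- unique(round(exp(seq(log(lo), log(n / 4), length.out = 12))))
  }
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < order + 2L)) stop("minimum scale must be >= order + 2")
  if (any(scales > n / 4)) {
    warning("dropping scales larger than N/4")
    scales <- scales[scales <= n / 4]
  }
  if (length(scales) < 3) stop("need at least 3 usable scales")
  y <- cumsum(x - mean(x))
  Fv <- vapply(scales, function(s) {
    nw <- floor(n / s)
    idx <- seq_len(nw * s)
    t <- seq_len(s)
    X <- outer(t, 0:order, `^`)
    # residual maker applied per window
    H <- X %*% solve(crossprod(X), t(X))
    seg <- matrix(y[idx], nrow = s)
    res <- seg - H %*% seg
    sqrt(mean(res^2))
  }, numeric(1))
  fit <- lm(log(Fv) ~ log(scales))
  structure(list(scales = scales, F = Fv, alpha = unname(coef(fit)[2]),
                 order = order),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> %d scales (%d..%d), order %d; alpha = %.3f\n",
              length(x$scales), min(x$scales), max(x$scales), x$order, x$alpha))
  invisible(x)
}

#' @export
plot.dfa_result <- function(x, ...) {
  graphics::plot(log10(x$scales), log10(x$F), type = "b",
                 xlab = "log10 scale", ylab = "log10 F(s)", ...)
  invisible(x)
}
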