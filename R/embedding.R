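#' Delay (Takens) embedding
#'
#' Reconstructs a `dim`-dimensional phase space from a scalar series by
#' time-shifted copies: the state attached to sample `t` is
#' `(x[t-(dim-1)*tau], ..., x[t-tau], x[t])` (backward convention, so a
#' state's index is the index of its newest coordinate and predictions at
#' horizon `h` target sample `t + h`). Columns are ordered oldest to newest.
#'
#' @param ts `nlts` or numeric vector of length `N > (dim-1)*tau`.
#' @param dim embedding dimension (>= 1).
#' @param tau embedding delay in samples (>= 1).
#' @return A `phase_space` object: an `n x dim` state matrix with
#'   `n = N - (dim-1)*tau` rows and attributes `dim`, `tau`,
#'   `source_length`, `fs`. Row `i` is the state ending at sample
#'   `i + (dim-1)*tau` of the input.
#' @examples
#' delay_embed(c(1, 2, 3, 4, 5), dim = 2, tau = 1)
#' @export
delay_embed <- function(ts, dim, tau = 1) {
  x <- ts_values(ts)
  dim <- as.integer(dim)
  tau <- as.integer(tau)
  stopifnot(dim >= 1L, tau >= 1L)
  n <- length(x) - (dim - 1L) * tau
  if (n < 1L)
    stop(sprintf("series too short: need at least %d samples for dim=%d, tau=%d",
                 (dim - 1L) * tau + 1L, dim, tau))
  states <- matrix(0, n, dim)
  for (j in seq_len(dim)) {
    # column j holds x[t - (dim-j)*tau]; column dim is the newest sample
    off <- (dim - j) * tau
    states[, j] <- x[seq_len(n) + (dim - 1L) * tau - off]
  }
  structure(states, dim_embed = dim, tau = tau, source_length = length(x),
            fs = ts_fs(ts), class = c("phase_space", "matrix", "array"))
}

#' @export
print.phase_space <- function(x, ...) {
  cat(sprintf("<phase_space> %d states, dim %d, tau %d (from %d samples)\n",
              nrow(x), attr(x, "dim_embed"), attr(x, "tau"),
              attr(x, "source_length")))
  invisible(x)
}

ps_states <- function(ps) {
  if (inherits(ps, "phase_space")) {
    m <- unclass(ps)
    attributes(m) <- list(dim = base::dim(m))
    return(m)
  }
  as.matrix(ps)
}

#' Exact neighbor search in phase space
#'
#' Finds, for every state, its neighbors under the chosen norm, either all
#' states within a fixed radius `eps` or the `k` nearest, always excluding
#' temporal neighbors closer than the Theiler window. The search is exact
#' (brute-force pairwise distances); empty neighborhoods are reported, not
#' errors.
#'
#' @param ps a `phase_space` (or plain state matrix).
#' @param eps neighborhood radius in data units (radius mode).
#' @param k neighbor count (k-nearest mode); give exactly one of `eps`, `k`.
#' @param norm `"maximum"` (default) or `"euclidean"`.
#' @param theiler Theiler exclusion window `w`: pairs with `|i - j| <= w`
#'   are never neighbors.
#' @return A `neighbor_structure` list: `neighbors` (list of 1-based index
#'   vectors; in k-mode also `distances`), plus the query parameters.
#' @export
find_neighbors <- function(ps, eps = NULL, k = NULL,
                           norm = c("maximum", "euclidean"), theiler = 0) {
  norm <- match.arg(norm)
  states <- ps_states(ps)
  theiler <- as.integer(theiler)
  stopifnot(theiler >= 0L)
  if (is.null(eps) == is.null(k))
    stop("give exactly one of 'eps' (radius mode) or 'k' (count mode)")
  if (!is.null(eps)) {
    stopifnot(eps > 0)
    nb <- nn_radius_cpp(states, eps, theiler, norm == "maximum")
    res <- list(mode = "radius", eps = eps, neighbors = nb)
  } else {
    k <- as.integer(k)
    stopifnot(k >= 1L)
    r <- nn_knn_cpp(states, k, theiler, norm == "maximum")
    nb <- lapply(seq_len(nrow(states)), function(i) {
      v <- r$idx[i, ]
      v[!is.na(v)]
    })
    res <- list(mode = "count", k = k, neighbors = nb,
                distances = r$dist)
  }
  res$norm <- norm
  res$theiler <- theiler
  structure(res, class = "neighbor_structure")
}

#' @export
print.neighbor_structure <- function(x, ...) {
  sizes <- lengths(x$neighbors)
  cat(sprintf("<neighbor_structure> %d states, %s mode (%s norm, theiler %d); neighbors/state: median %g, %d empty\n",
              length(x$neighbors),
              x$mode, x$norm, x$theiler, median(sizes), sum(sizes == 0)))
  invisible(x)
}

#' Auto-mutual information curve
#'
#' Mutual information between a series and its lagged copy for lags
#' `0..max_lag`, with either the binned (shared equal-width discretization,
#' Freedman-Diaconis bins by default) or the Kraskov nearest-neighbor
#' estimator. `AMI(0)` equals the marginal entropy of the discretized series
#' (binned estimator). The first strict local minimum of the curve is the
#' classic choice of embedding delay.
#'
#' @param ts `nlts` or numeric vector.
#' @param max_lag largest lag (samples), must be below `N/2`.
#' @param estimator `"binned"` or `"knn"`.
#' @param bins bin count for the binned estimator, or `"auto"`
#'   (Freedman-Diaconis).
#' @param k neighbor count for the knn estimator.
#' @return An `ami_curve` list with `lag`, `ami` (bits) and `first_minimum`
#'   (`NA` if the curve has no strict local minimum).
#' @export
auto_mutual_information <- function(ts, max_lag = 50,
                                    estimator = c("binned", "knn"),
                                    bins = "auto", k = 4) {
  estimator <- match.arg(estimator)
  x <- ts_values(ts)
  n <- length(x)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n / 2) stop("'max_lag' must be below N/2")
  if (sd(x) == 0) stop("constant series: entropy is zero and AMI undefined")
  ami <- numeric(max_lag + 1L)
  if (estimator == "binned") {
    B <- if (identical(bins, "auto")) freedman_diaconis_bins(x) else as.integer(bins)
    ix <- bin_indices(x, B)
    for (lag in 0:max_lag) {
      a <- ix[seq_len(n - lag)]
      b <- ix[seq_len(n - lag) + lag]
      ami[lag + 1L] <- discrete_mi(a, b, B)
    }
  } else {
    for (lag in 0:max_lag) {
      a <- x[seq_len(n - lag)]
      b <- x[seq_len(n - lag) + lag]
      ami[lag + 1L] <- mutual_information(a, b, estimator = "ksg", k = k)$value
    }
  }
  fm <- NA_integer_
  if (max_lag >= 2) {
    for (lag in 1:(max_lag - 1L)) {
      if (ami[lag + 1L] < ami[lag] && ami[lag + 1L] < ami[lag + 2L]) {
        fm <- lag
        break
      }
    }
  }
  structure(list(lag = 0:max_lag, ami = ami, first_minimum = fm,
                 estimator = estimator),
            class = "ami_curve")
}

#' @export
print.ami_curve <- function(x, ...) {
  cat(sprintf("<ami_curve> lags 0..%d (%s estimator); AMI(0) = %.3f bits; first local minimum at lag %s\n",
              max(x$lag), x$estimator, x$ami[1],
              if (is.na(x$first_minimum)) "none" else x$first_minimum))
  invisible(x)
}

#' @export
plot.ami_curve <- function(x, ...) {
  graphics::plot(x$lag, x$ami, type = "b", xlab = "lag (samples)",
                 ylab = "AMI (bits)", ...)
  if (!is.na(x$first_minimum))
    graphics::abline(v = x$first_minimum, lty = 2)
  invisible(x)
}

#' False nearest neighbors across embedding dimensions
#'
#' Kennel's criterion for choosing the embedding dimension: for each
#' candidate dimension `d`, every state's nearest neighbor at dimension `d`
#' is re-examined at `d + 1`; it is a false neighbor if the distance gained
#' by the extra coordinate exceeds `Rtol` times the dimension-`d` distance,
#' or if the dimension-`d+1` distance exceeds `Atol` standard deviations of
#' the series (neighbors that were never close). The suggested dimension is
#' the lowest one whose false-neighbor fraction falls below `drop`.
#'
#' @param ts `nlts` or numeric vector (non-constant).
#' @param tau embedding delay (samples).
#' @param dims integer vector of dimensions to test (default 1:9).
#' @param Rtol distance-ratio threshold (default 10).
#' @param Atol loneliness threshold in SD units (default 2).
#' @param theiler Theiler window for the neighbor search.
#' @param drop fraction below which FNN counts as "dropped to zero"
#'   (default 0.01).
#' @return An `fnn_curve` list with `dims`, `fnn` (fractions in `[0,1]`)
#'   and `suggested_dim` (`NA` if no dimension drops below `drop`).
#' @export
false_nearest_neighbors <- function(ts, tau, dims = 1:9, Rtol = 10, Atol = 2,
                                    theiler = 0, drop = 0.01) {
  x <- ts_values(ts)
  if (sd(x) == 0)
    stop("constant series: the Atol criterion is degenerate (zero SD)")
  stopifnot(Rtol > 0, Atol > 0)
  dims <- sort(as.integer(dims))
  need <- max(dims) * as.integer(tau) + 1L
  if (length(x) <= need)
    stop(sprintf("series too short: need > %d samples to test dim %d",
                 need, max(dims)))
  sdx <- sd(x)
  fnn <- vapply(dims, function(d) {
    # embed at d+1 and treat the newest coordinate as the one gained going
    # d -> d+1, so the criterion extends the state forward in time (the
    # backward extension amplifies along the contracting direction, whose
    # rate dwarfs the expansion rate on dissipative attractors, and flags
    # true neighbors as false)
    E <- ps_states(delay_embed(x, d + 1L, tau))
    E <- cbind(E[, d + 1L], E[, seq_len(d), drop = FALSE])
    # distances at rounding level (exactly periodic data) are duplicates,
    # not candidates for the ratio test
    r <- fnn_cpp(E, Rtol, Atol * sdx, as.integer(theiler), TRUE, 1e-9 * sdx)
    if (r[1] == 0) NA_real_ else r[2] / r[1]
  }, numeric(1))
  below <- which(fnn < drop)
  structure(list(dims = dims, fnn = fnn,
                 suggested_dim = if (length(below)) dims[below[1L]] else NA_integer_,
                 Rtol = Rtol, Atol = Atol, drop = drop),
            class = "fnn_curve")
}

#' @export
print.fnn_curve <- function(x, ...) {
  cat(sprintf("<fnn_curve> dims %d..%d; suggested dim: %s (FNN < %g%%)\n",
              min(x$dims), max(x$dims),
              if (is.na(x$suggested_dim)) "none" else x$suggested_dim,
              100 * x$drop))
  print(round(stats::setNames(x$fnn, x$dims), 4))
  invisible(x)
}

#' @export
plot.fnn_curve <- function(x, ...) {
  graphics::plot(x$dims, 100 * x$fnn, type = "b", xlab = "embedding dimension",
                 ylab = "FNN (%)", ...)
  invisible(x)
}

#' Ragwitz embedding optimization for stochastic signals
#'
#' Jointly chooses embedding dimension and delay by minimizing the
#' root-mean-square error of a local-constant (nearest-neighbor) one-step
#' predictor over a `(dim, tau)` grid: each state's next sample is predicted
#' by the average successor of its `k` nearest neighbors. Suited to
#' stochastic (finite-memory Markov) signals where false-nearest-neighbor
#' counts are unreliable.
#'
#' @param ts `nlts` or numeric vector.
#' @param dims dimensions to scan (default 2:9; include 1 for Markov-order-1
#'   signals).
#' @param taus delays to scan; default spans 10--100% of the autocorrelation
#'   time in 5 steps.
#' @param k neighbor count of the local predictor.
#' @param horizon prediction horizon (samples).
#' @param theiler Theiler window.
#' @param tie_tol relative RMSPE tolerance within which grid cells count as
#'   tied with the minimum (default 1%); among tied cells the smallest
#'   dimension, then the smallest delay, is chosen. On noisy grids the
#'   strict argmin wanders between statistically indistinguishable cells,
#'   and parsimony should win those ties.
#' @return A `ragwitz_grid` list with the RMSPE matrix (`dims` x `taus`),
#'   and the chosen `dim` and `tau`.
#' @export
ragwitz_optimize <- function(ts, dims = 2:9, taus = NULL, k = 30, horizon = 1,
                             theiler = 0, tie_tol = 0.01) {
  x <- ts_values(ts)
  dims <- as.integer(dims)
  if (is.null(taus)) {
    act <- autocorrelation_time(x)
    taus <- unique(pmax(1L, as.integer(round(act * seq(0.1, 1, length.out = 5)))))
  }
  taus <- as.integer(taus)
  stopifnot(length(dims) >= 1, length(taus) >= 1, k >= 1, horizon >= 1)
  g <- ragwitz_cpp(x, dims, taus, as.integer(k), as.integer(horizon),
                   as.integer(theiler))
  dimnames(g) <- list(dim = dims, tau = taus)
  if (all(is.na(g))) stop("all grid cells empty: series too short for the grid")
  tied <- which(g <= min(g, na.rm = TRUE) * (1 + tie_tol), arr.ind = TRUE)
  best <- tied[order(tied[, 1], tied[, 2]), , drop = FALSE][1, ]
  structure(list(rmspe = g, dim = dims[best[1]], tau = taus[best[2]],
                 dims = dims, taus = taus, k = k, horizon = horizon,
                 tie_tol = tie_tol),
            class = "ragwitz_grid")
}

#' @export
print.ragwitz_grid <- function(x, ...) {
  cat(sprintf("<ragwitz_grid> RMSPE over %d dims x %d taus; optimum dim %d, tau %d (RMSPE %.4g)\n",
              length(x$dims), length(x$taus), x$dim, x$tau,
              x$rmspe[as.character(x$dim), as.character(x$tau)]))
  invisible(x)
}

#' Local-constant phase-space prediction
#'
#' Predicts the sample `horizon` steps after each query state as the mean of
#' the `horizon`-step successors of all states within radius `eps` of the
#' query (Theiler-excluded), and reports the root-mean-square prediction
#' error over the queries. Queries with empty neighborhoods are skipped and
#' counted.
#'
#' @param ps a `phase_space` built with [delay_embed()] (the source series
#'   is needed for the successors, so pass the embedding, not a bare
#'   matrix).
#' @param ts the source series the embedding was built from.
#' @param eps neighborhood radius (data units).
#' @param horizon prediction horizon (samples).
#' @param queries 1-based state rows to predict (default: all with a
#'   target).
#' @param theiler Theiler window.
#' @param norm distance norm.
#' @return List with `pred`, `truth`, `rmspe` and `n_skipped`.
#' @export
nonlinear_predict <- function(ps, ts, eps, horizon = 1, queries = NULL,
                              theiler = 0, norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  stopifnot(inherits(ps, "phase_space"), eps > 0, horizon >= 1)
  x <- ts_values(ts)
  d <- attr(ps, "dim_embed")
  tau <- attr(ps, "tau")
  n <- nrow(ps)
  if (is.null(queries)) queries <- seq_len(max(0L, n - as.integer(horizon)))
  r <- predict_radius_cpp(ps_states(ps), x, d, tau, eps, as.integer(horizon),
                          as.integer(queries), as.integer(theiler),
                          norm == "maximum")
  r
}

#' Space-time separation curves
#'
#' For each temporal separation `dt`, the given quantiles of the spatial
#' distance between state pairs exactly `dt` apart. For signals with
#' temporal correlation the curves rise with `dt` before leveling off; the
#' suggested Theiler window is the first `dt` where the median curve
#' plateaus (slope over a 5-sample window below 1% of the attractor
#' diameter per sample).
#'
#' @param ps `phase_space` or state matrix.
#' @param fractions quantile levels in (0,1).
#' @param max_dt largest temporal separation scanned.
#' @param norm distance norm.
#' @return A `stsep_curves` list: `dt`, matrix `eps_q` (rows = `dt`,
#'   columns = fractions) and `suggested_theiler`.
#' @export
space_time_separation <- function(ps, fractions = c(0.25, 0.5, 0.75),
                                  max_dt = NULL, norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  stopifnot(all(fractions > 0), all(fractions < 1))
  states <- ps_states(ps)
  n <- nrow(states)
  if (is.null(max_dt)) max_dt <- min(n - 1L, 100L)
  max_dt <- as.integer(max_dt)
  q <- matrix(NA_real_, max_dt, length(fractions))
  for (dt in seq_len(max_dt)) {
    a <- states[seq_len(n - dt), , drop = FALSE]
    b <- states[seq_len(n - dt) + dt, , drop = FALSE]
    dd <- abs(a - b)
    dist <- if (norm == "maximum") do.call(pmax, as.data.frame(dd))
            else sqrt(rowSums(dd^2))
    q[dt, ] <- quantile(dist, fractions)
  }
  med <- q[, which.min(abs(fractions - 0.5))]
  diam <- attractor_diameter(states, norm)
  sug <- NA_integer_
  w <- 5L
  if (max_dt > w) {
    for (dt in seq_len(max_dt - w)) {
      slope <- (med[dt + w] - med[dt]) / w
      if (abs(slope) < 0.01 * diam) { sug <- dt; break }
    }
  }
  structure(list(dt = seq_len(max_dt), fractions = fractions, eps_q = q,
                 suggested_theiler = sug),
            class = "stsep_curves")
}

#' @export
print.stsep_curves <- function(x, ...) {
  cat(sprintf("<stsep_curves> dt 1..%d, quantiles %s; suggested Theiler window: %s\n",
              max(x$dt), paste(x$fractions, collapse = "/"),
              if (is.na(x$suggested_theiler)) "none" else x$suggested_theiler))
  invisible(x)
}

#' @export
plot.stsep_curves <- function(x, ...) {
  graphics::matplot(x$dt, x$eps_q, type = "l", lty = 1,
                    xlab = "temporal separation dt (samples)",
                    ylab = "spatial separation", ...)
  if (!is.na(x$suggested_theiler)) graphics::abline(v = x$suggested_theiler, lty = 2)
  invisible(x)
}

#' Automatic embedding parameter choice
#'
#' Deterministic pathway: delay from the first local minimum of the
#' auto-mutual information, then dimension from the false-nearest-neighbor
#' curve at that delay. Stochastic pathway: joint `(dim, tau)` optimization
#' by the Ragwitz predictor criterion.
#'
#' @param ts `nlts` or numeric vector.
#' @param method `"deterministic"` or `"stochastic"`.
#' @param max_lag lag range scanned for the AMI minimum (deterministic).
#' @param dims dimension range scanned.
#' @param ... passed on to [false_nearest_neighbors()] or
#'   [ragwitz_optimize()].
#' @return List with the chosen `dim` and `tau` plus the supporting curves.
#' @export
optimize_embedding <- function(ts, method = c("deterministic", "stochastic"),
                               max_lag = 50, dims = NULL, ...) {
  method <- match.arg(method)
  if (method == "deterministic") {
    if (is.null(dims)) dims <- 1:9
    ami <- auto_mutual_information(ts, max_lag = max_lag)
    tau <- ami$first_minimum
    if (is.na(tau))
      stop("auto-mutual information has no local minimum in the scanned lags; give tau explicitly")
    fnn <- false_nearest_neighbors(ts, tau = tau, dims = dims, ...)
    list(method = method, dim = fnn$suggested_dim, tau = tau,
         ami = ami, fnn = fnn)
  } else {
    if (is.null(dims)) dims <- 2:9
    rg <- ragwitz_optimize(ts, dims = dims, ...)
    list(method = method, dim = rg$dim, tau = rg$tau, grid = rg)
  }
}
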