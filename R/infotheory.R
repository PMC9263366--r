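#' Freedman-Diaconis bin count
#'
#' Bin width `2 * IQR * n^(-1/3)`, count `ceiling(range / width)`. Invariant
#' under rescaling of the data. With a degenerate (zero) interquartile range
#' the rule is unusable and a Sturges-like fallback `ceiling(log2(n)) + 1`
#' is returned with a warning.
#'
#' @param x numeric vector.
#' @return Integer bin count (>= 2).
#' @export
freedman_diaconis_bins <- function(x) {
  x <- ts_values(x)
  n <- length(x)
  iqr <- IQR(x)
  if (iqr == 0) {
    warning("zero IQR: falling back to a Sturges-like bin count")
    return(max(2L, as.integer(ceiling(log2(n)) + 1L)))
  }
  width <- 2 * iqr * n^(-1 / 3)
  max(2L, as.integer(ceiling(diff(range(x)) / width)))
}

# Equal-width bin indices over the data range (1..bins).
bin_indices <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant input: zero range under binning")
  ix <- findInterval(x, seq(rng[1], rng[2], length.out = bins + 1L),
                     rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(ix)
}

# Plug-in Shannon entropy (bits) of integer codes.
discrete_entropy <- function(ix) {
  p <- tabulate(ix)
  p <- p[p > 0] / length(ix)
  -sum(p * log2(p))
}

# Plug-in MI (bits) between two integer codes on a B x B grid.
discrete_mi <- function(a, b, B) {
  joint <- tabulate((a - 1L) * B + b, nbins = B * B)
  n <- length(a)
  pj <- joint[joint > 0] / n
  Hj <- -sum(pj * log2(pj))
  discrete_entropy(a) + discrete_entropy(b) - Hj
}

#' Binned Shannon entropy
#'
#' Plug-in entropy of the equal-width-binned sample, in bits. For continuous
#' data the `differential` field adds `log2(bin width)` so that the estimate
#' approximates the differential entropy of the underlying density (the raw
#' binned entropy grows with the bin count; the corrected one stabilizes).
#' Local (per-sample) information `-log2 p(bin(x_t))` is returned alongside;
#' its mean equals the global value.
#'
#' @param x `nlts` or numeric vector.
#' @param bins bin count, or `"auto"` for the Freedman-Diaconis rule.
#' @return An `info_estimate` with `value` (Shannon entropy, bits),
#'   `differential` (width-corrected, bits), `local`, `bins`.
#' @export
entropy_binned <- function(x, bins = "auto") {
  x <- ts_values(x)
  if (diff(range(x)) == 0)
    stop("constant input: entropy under auto-binning is undefined (zero range)")
  B <- if (identical(bins, "auto")) freedman_diaconis_bins(x) else as.integer(bins)
  stopifnot(B >= 2)
  ix <- bin_indices(x, B)
  p <- tabulate(ix, nbins = B) / length(x)
  local <- -log2(p[ix])
  width <- diff(range(x)) / B
  H <- mean(local)
  structure(list(value = H, differential = H + log2(width), local = local,
                 estimator = "binned", bins = B, base = 2),
            class = "info_estimate")
}

#' Kozachenko-Leonenko nearest-neighbor differential entropy
#'
#' Differential entropy (bits) from k-th nearest-neighbor distances under
#' the maximum norm:
#' \deqn{\hat H = \psi(N) - \psi(k) + \log_2 c_d + \frac{d}{N} \sum_i \log_2 \varepsilon_i}
#' with \eqn{c_d = 2^d} the unit-ball volume. Duplicate points make a k-th
#' distance zero; by default an infinitesimal deterministic jitter (scaled
#' far below data resolution, derived from `jitter_seed`) breaks the ties,
#' or the estimator fails if `on_ties = "error"`.
#'
#' @param x numeric vector or matrix (rows = samples).
#' @param k neighbor count (mass), default 4.
#' @param on_ties `"jitter"` or `"error"`.
#' @param jitter_seed seed for the tie-breaking jitter.
#' @return An `info_estimate` with `value` (bits) and `local` values whose
#'   mean equals the global estimate.
#' @export
entropy_knn <- function(x, k = 4, on_ties = c("jitter", "error"),
                        jitter_seed = 1) {
  on_ties <- match.arg(on_ties)
  X <- if (is.matrix(x)) x else matrix(ts_values(x), ncol = 1)
  n <- nrow(X)
  d <- ncol(X)
  k <- as.integer(k)
  stopifnot(k >= 1, n > k)
  eps <- knn_dist_cpp(X, k, TRUE)
  if (any(eps == 0)) {
    if (on_ties == "error") stop("duplicate points: k-th neighbor distance is zero")
    scale <- max(apply(X, 2, function(c) diff(range(c))), .Machine$double.eps)
    X <- X + with_seed(jitter_seed,
                       matrix(runif(n * d, -1, 1), n, d)) * scale * 1e-10
    eps <- knn_dist_cpp(X, k, TRUE)
  }
  local <- (digamma(n) - digamma(k)) / log(2) + d + d * log2(eps)
  structure(list(value = mean(local), local = local, estimator = "knn",
                 k = k, base = 2),
            class = "info_estimate")
}

#' Mutual information
#'
#' Shared information (bits) between two equal-length samples. The binned
#' estimator computes `H(X) + H(Y) - H(X, Y)` on a shared equal-width grid;
#' the `"ksg"` estimator is the Kraskov-Stoegbauer-Grassberger algorithm-1
#' nearest-neighbor estimator (max-norm neighbor counting), which is far
#' less biased for continuous data. Local per-sample values are returned;
#' their mean equals the global estimate.
#'
#' @param x,y numeric vectors of equal length (or matrices with equal row
#'   counts for the ksg estimator).
#' @param estimator `"binned"` or `"ksg"`.
#' @param bins bin count or `"auto"` (binned).
#' @param k neighbor count (ksg), default 4.
#' @param on_ties,jitter_seed tie handling for the ksg estimator, as in
#'   [entropy_knn()].
#' @return An `info_estimate` with `value` (bits) and `local`.
#' @export
mutual_information <- function(x, y, estimator = c("binned", "ksg"),
                               bins = "auto", k = 4,
                               on_ties = c("jitter", "error"),
                               jitter_seed = 1) {
  estimator <- match.arg(estimator)
  on_ties <- match.arg(on_ties)
  X <- if (is.matrix(x)) x else matrix(ts_values(x), ncol = 1)
  Y <- if (is.matrix(y)) y else matrix(ts_values(y), ncol = 1)
  if (nrow(X) != nrow(Y)) stop("'x' and 'y' must have equal lengths")
  n <- nrow(X)
  if (estimator == "binned") {
    if (ncol(X) > 1 || ncol(Y) > 1)
      stop("the binned estimator expects scalar variables")
    B <- if (identical(bins, "auto"))
      max(freedman_diaconis_bins(X[, 1]), freedman_diaconis_bins(Y[, 1]))
    else as.integer(bins)
    a <- bin_indices(X[, 1], B)
    b <- bin_indices(Y[, 1], B)
    joint <- tabulate((a - 1L) * B + b, nbins = B * B) / n
    px <- tabulate(a, nbins = B) / n
    py <- tabulate(b, nbins = B) / n
    local <- log2(joint[(a - 1L) * B + b] / (px[a] * py[b]))
    structure(list(value = mean(local), local = local, estimator = "binned",
                   bins = B, base = 2),
              class = "info_estimate")
  } else {
    k <- as.integer(k)
    stopifnot(k >= 1, n > k)
    r <- ksg_counts_cpp(X, Y, k)
    if (any(r$eps == 0)) {
      if (on_ties == "error") stop("duplicate joint points: zero k-th distance")
      jit <- function(M, s) {
        scale <- max(apply(M, 2, function(c) diff(range(c))),
                     .Machine$double.eps)
        M + with_seed(s, matrix(runif(length(M), -1, 1), nrow(M))) * scale * 1e-10
      }
      r <- ksg_counts_cpp(jit(X, jitter_seed), jit(Y, jitter_seed + 1L), k)
    }
    local <- (digamma(k) + digamma(n) - digamma(r$nx + 1) -
                digamma(r$ny + 1)) / log(2)
    structure(list(value = mean(local), local = local, estimator = "ksg",
                   k = k, base = 2),
              class = "info_estimate")
  }
}

#' Active information storage
#'
#' Mutual information between a process's embedded past state
#' `(x_{t-(d-1)tau}, ..., x_{t-tau}, x_t)` and its next sample `x_{t+1}`:
#' how much of the information in the next observation is predictable from
#' the process's own history. Local per-sample storage values are returned;
#' their mean equals the global estimate.
#'
#' @param ts `nlts` or numeric vector.
#' @param dim history embedding dimension (default 1).
#' @param tau history embedding delay (default 1).
#' @param estimator `"binned"` or `"ksg"`.
#' @param bins,k estimator parameters as in [mutual_information()].
#' @return An `info_estimate` with `value` (bits) and `local`.
#' @export
active_information_storage <- function(ts, dim = 1, tau = 1,
                                       estimator = c("binned", "ksg"),
                                       bins = "auto", k = 4) {
  estimator <- match.arg(estimator)
  x <- ts_values(ts)
  ps <- delay_embed(x, dim, tau)
  n <- nrow(ps) - 1L
  if (n < 2) stop("series too short to embed the past state")
  past <- ps_states(ps)[seq_len(n), , drop = FALSE]
  nxt <- x[seq_len(n) + (dim - 1L) * tau + 1L]
  if (estimator == "binned") {
    B <- if (identical(bins, "auto")) freedman_diaconis_bins(x) else as.integer(bins)
    # shared discretization of every coordinate over the full series range
    rng <- range(x)
    edges <- seq(rng[1], rng[2], length.out = B + 1L)
    code1 <- function(v) as.integer(findInterval(v, edges,
                                                 rightmost.closed = TRUE,
                                                 all.inside = TRUE))
    pcode <- code1(past[, 1])
    if (ncol(past) > 1) {
      for (j in 2:ncol(past)) pcode <- (pcode - 1L) * B + code1(past[, j])
    }
    pcode <- match(pcode, sort(unique(pcode)))  # compact joint alphabet
    ncode <- code1(nxt)
    Bp <- max(pcode)
    joint <- tabulate((pcode - 1L) * B + ncode, nbins = Bp * B) / n
    pp <- tabulate(pcode, nbins = Bp) / n
    pn <- tabulate(ncode, nbins = B) / n
    local <- log2(joint[(pcode - 1L) * B + ncode] / (pp[pcode] * pn[ncode]))
    structure(list(value = mean(local), local = local, estimator = "binned",
                   bins = B, dim = dim, tau = tau, base = 2),
              class = "info_estimate")
  } else {
    mi <- mutual_information(past, matrix(nxt, ncol = 1), estimator = "ksg",
                             k = k)
    mi$dim <- dim
    mi$tau <- tau
    mi
  }
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("<info_estimate> %.4f bits (%s estimator%s)%s\n",
              x$value, x$estimator,
              if (x$estimator == "binned") sprintf(", %d bins", x$bins)
              else sprintf(", k = %d", x$k),
              if (!is.null(x$differential))
                sprintf("; differential-corrected %.4f bits", x$differential)
              else ""))
  invisible(x)
}
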