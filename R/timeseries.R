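#' Sampled time series
#'
#' Light container for a real-valued sampled signal: a numeric vector of
#' values, an optional sampling rate in Hz and a label. All analysis
#' functions in the package accept either an `nlts` object or a bare numeric
#' vector (in which case the sampling rate is unknown and sample-based units
#' are used).
#'
#' @param values numeric vector, all finite, length >= 2.
#' @param fs sampling rate in Hz, or `NULL` if unknown.
#' @param label character label for the channel.
#' @return An object of class `nlts`.
#' @examples
#' x <- nlts(sin(2 * pi * 3 * seq(0, 2, by = 0.01)), fs = 100, label = "sine")
#' print(x)
#' @export
nlts <- function(values, fs = NULL, label = "x") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a time series needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("time series values must all be finite")
  if (!is.null(fs)) {
    fs <- as.numeric(fs)
    if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
      stop("'fs' must be a positive scalar (Hz)")
  }
  structure(list(values = values, fs = fs, label = as.character(label)[1L]),
            class = "nlts")
}

#' @export
print.nlts <- function(x, ...) {
  cat(sprintf("<nlts> '%s': %d samples%s, range [%.4g, %.4g]\n",
              x$label, length(x$values),
              if (is.null(x$fs)) "" else sprintf(" @ %g Hz (%.4g s)",
                                                 x$fs, length(x$values) / x$fs),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.nlts <- function(x, ...) {
  t <- if (is.null(x$fs)) seq_along(x$values) else (seq_along(x$values) - 1) / x$fs
  graphics::plot(t, x$values, type = "l",
                 xlab = if (is.null(x$fs)) "sample" else "time (s)",
                 ylab = x$label, ...)
  invisible(x)
}

#' @export
as.numeric.nlts <- function(x, ...) x$values

# Accept nlts or numeric; return numeric vector.
ts_values <- function(ts) {
  if (inherits(ts, "nlts")) return(ts$values)
  if (is.numeric(ts)) return(as.numeric(ts))
  stop("expected an 'nlts' object or a numeric vector")
}

ts_fs <- function(ts) if (inherits(ts, "nlts")) ts$fs else NULL

# Evaluate code under a temporary seed; NULL seed leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Autocorrelation time of a series
#'
#' The lag of the first zero crossing of the sample autocorrelation function.
#' If the ACF does not cross zero within `N/2` lags, `N/10` is returned. Used
#' as the default scale for Theiler windows (twice the autocorrelation time)
#' and for the delay range of the Ragwitz embedding optimizer.
#'
#' @param ts `nlts` or numeric vector.
#' @return Integer lag in samples.
#' @export
autocorrelation_time <- function(ts) {
  x <- ts_values(ts)
  n <- length(x)
  maxlag <- floor(n / 2)
  a <- acf(x, lag.max = maxlag, plot = FALSE)$acf[-1]
  idx <- which(a <= 0)
  if (length(idx) == 0L) return(max(1L, floor(n / 10)))
  as.integer(idx[1L])
}

# Attractor diameter of a state matrix under the given norm.
attractor_diameter <- function(states, norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  rng <- apply(states, 2, range)
  ext <- rng[2, ] - rng[1, ]
  if (norm == "maximum") max(ext) else sqrt(sum(ext^2))
}

norm_is_max <- function(norm) {
  norm <- match.arg(norm, c("maximum", "euclidean"))
  norm == "maximum"
}
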