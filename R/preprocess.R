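#' Preprocess a time series
#'
#' Applies, in fixed order, (1) windowing to a time region of interest,
#' (2) linear detrending, (3) zero-phase Butterworth filtering (the filter
#' is run forward and backward, so it has zero phase shift and double the
#' nominal order of attenuation), (4) z-score normalization. Normalization
#' is applied last so that downstream radii expressed in percent of the
#' standard deviation refer to the analyzed series. The applied steps are
#' recorded in the result's `log` attribute.
#'
#' @param ts `nlts` (a sampling rate is required for windows in seconds and
#'   for filtering) or numeric vector.
#' @param window numeric length-2 region of interest, in seconds when the
#'   series has a sampling rate, otherwise in samples; `NULL` keeps all.
#' @param detrend `"none"` or `"linear"` (least-squares line removal).
#' @param filter `NULL` for no filtering, or a list with fields `order`
#'   (e.g. 4), `cutoff` (Hz; length 2 for band filters) and `type`
#'   (`"low"`, `"high"`, `"pass"`, `"stop"`). Cutoffs must be below the
#'   Nyquist frequency.
#' @param normalize `"none"` or `"zscore"`.
#' @return An [nlts] with attribute `log` listing the applied operations.
#' @export
preprocess <- function(ts, window = NULL, detrend = c("none", "linear"),
                       filter = NULL, normalize = c("none", "zscore")) {
  detrend <- match.arg(detrend)
  normalize <- match.arg(normalize)
  x <- ts_values(ts)
  fs <- ts_fs(ts)
  label <- if (inherits(ts, "nlts")) ts$label else "x"
  log <- character(0)
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    idx <- if (!is.null(fs)) {
      max(1L, floor(window[1] * fs) + 1L):min(length(x), ceiling(window[2] * fs))
    } else {
      max(1L, as.integer(window[1])):min(length(x), as.integer(window[2]))
    }
    if (length(idx) < 2) stop("window selects fewer than 2 samples")
    x <- x[idx]
    log <- c(log, sprintf("window [%g, %g]", window[1], window[2]))
  }
  if (detrend == "linear") {
    t <- seq_along(x)
    x <- unname(stats::residuals(lm(x ~ t)))
    log <- c(log, "linear detrend")
  }
  if (!is.null(filter)) {
    if (is.null(fs)) stop("filtering requires a sampling rate")
    stopifnot(is.list(filter), !is.null(filter$cutoff))
    order <- if (is.null(filter$order)) 4L else as.integer(filter$order)
    type <- if (is.null(filter$type)) "low" else filter$type
    W <- filter$cutoff / (fs / 2)
    if (any(W >= 1)) stop("filter cutoff at or above the Nyquist frequency")
    bf <- signal::butter(order, W, type = type)
    x <- as.numeric(signal::filtfilt(bf, x))
    log <- c(log, sprintf("butterworth order %d %s @ %s Hz (bidirectional)",
                          order, type, paste(filter$cutoff, collapse = "-")))
  }
  if (normalize == "zscore") {
    if (sd(x) == 0) stop("cannot z-score a constant series")
    x <- (x - mean(x)) / sd(x)
    log <- c(log, "zscore")
  }
  out <- nlts(x, fs = fs, label = label)
  attr(out, "log") <- log
  out
}
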