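#' Recurrence matrix
#'
#' Thresholded pairwise-distance matrix of a phase space:
#' `M[i, j] = 1` when states i and j are closer than the neighborhood size.
#' In `"epsilon"` mode a single global radius is used and the matrix is
#' symmetric; in `"rate"` mode each state gets its own radius, chosen as the
#' distance to its k-th admissible neighbor so that every row attains the
#' target recurrence rate (the matrix is then generally asymmetric).
#' Entries within the Theiler window of the main diagonal are cleared.
#'
#' @param ps `phase_space` or state matrix.
#' @param mode `"epsilon"` (fixed radius) or `"rate"` (target fill rate).
#' @param value the radius in data units (`"epsilon"` mode) or the target
#'   recurrence rate in percent (`"rate"` mode, default 5).
#' @param norm distance norm.
#' @param theiler Theiler window.
#' @return A `recurrence_matrix` list: binary matrix `M`, the mode and its
#'   parameter, per-point `radii` (rate mode), `norm`, `theiler`.
#' @export
recurrence_matrix <- function(ps, mode = c("epsilon", "rate"), value = NULL,
                              norm = c("maximum", "euclidean"), theiler = 0) {
  mode <- match.arg(mode)
  norm <- match.arg(norm)
  states <- ps_states(ps)
  n <- nrow(states)
  theiler <- as.integer(theiler)
  D <- state_dist_matrix(states, states, norm)
  radii <- NULL
  if (mode == "epsilon") {
    if (is.null(value)) stop("'value' (radius) is required in epsilon mode")
    stopifnot(value > 0)
    M <- (D <= value) * 1L
  } else {
    if (is.null(value)) value <- 5
    stopifnot(value > 0, value <= 100)
    if (value / 100 < 1 / (n - 1))
      stop(sprintf("rate %.3g%% is below the resolution 1/(n-1) of %d states",
                   value, n))
    adm <- abs(outer(seq_len(n), seq_len(n), `-`)) > theiler
    k <- max(1L, ceiling(value / 100 * (n - 1 - 2 * theiler)))
    radii <- vapply(seq_len(n), function(i) {
      dd <- sort(D[i, adm[i, ]])
      if (k > length(dd)) dd[length(dd)] else dd[k]
    }, numeric(1))
    # column-major recycling compares D[i, j] with radii[i]: row-wise radii
    M <- (D <= radii) * 1L
  }
  if (theiler > 0) {
    excl <- abs(outer(seq_len(n), seq_len(n), `-`)) <= theiler
    M[excl] <- 0L
  } else {
    diag(M) <- 1L
  }
  structure(list(M = M, mode = mode, value = value, radii = radii,
                 norm = norm, theiler = theiler),
            class = "recurrence_matrix")
}

# Dense pairwise distance matrix between two state sets (row-wise states).
state_dist_matrix <- function(A, B, norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  d <- ncol(A)
  if (ncol(B) != d) stop("state dimension mismatch between the two phase spaces")
  acc <- NULL
  for (c in seq_len(d)) {
    dd <- abs(outer(A[, c], B[, c], `-`))
    if (norm == "maximum") {
      acc <- if (is.null(acc)) dd else pmax(acc, dd)
    } else {
      acc <- if (is.null(acc)) dd^2 else acc + dd^2
    }
  }
  if (norm == "euclidean") sqrt(acc) else acc
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  n <- nrow(x$M)
  cat(sprintf("<recurrence_matrix> %d x %d, %s mode (%s), fill rate %.2f%% (theiler %d)\n",
              n, ncol(x$M), x$mode,
              if (x$mode == "epsilon") sprintf("eps = %.4g", x$value)
              else sprintf("target %.3g%%", x$value),
              100 * mean(x$M), x$theiler))
  invisible(x)
}

#' @export
plot.recurrence_matrix <- function(x, ...) {
  graphics::image(seq_len(nrow(x$M)), seq_len(ncol(x$M)), x$M,
                  col = c("white", "black"), xlab = "state i", ylab = "state j",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Cross-recurrence matrix of two phase spaces
#'
#' `M[i, j] = 1` when state i of the first system is within `eps` of state j
#' of the second. The two embeddings must share the same dimension; lengths
#' may differ.
#'
#' @param psA,psB phase spaces (or state matrices) of equal dimension.
#' @param eps radius in data units.
#' @param norm distance norm.
#' @return A `recurrence_matrix` (generally rectangular, no Theiler window).
#' @export
cross_recurrence <- function(psA, psB, eps, norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  stopifnot(eps > 0)
  D <- state_dist_matrix(ps_states(psA), ps_states(psB), norm)
  structure(list(M = (D <= eps) * 1L, mode = "epsilon", value = eps,
                 radii = NULL, norm = norm, theiler = 0L),
            class = "recurrence_matrix")
}

#' Joint recurrence matrix of two phase spaces
#'
#' Elementwise product of the two auto-recurrence matrices: a joint
#' recurrence requires both systems to recur at the same pair of times. The
#' two series must have equal numbers of states (dimensions may differ).
#'
#' @param psA,psB phase spaces with the same number of states.
#' @param epsA,epsB radii for the two auto-recurrence matrices.
#' @param norm distance norm.
#' @param theiler Theiler window applied to both.
#' @return A `recurrence_matrix`.
#' @export
joint_recurrence <- function(psA, psB, epsA, epsB = epsA,
                             norm = c("maximum", "euclidean"), theiler = 0) {
  norm <- match.arg(norm)
  A <- recurrence_matrix(psA, "epsilon", epsA, norm = norm, theiler = theiler)
  B <- recurrence_matrix(psB, "epsilon", epsB, norm = norm, theiler = theiler)
  if (!all(dim(A$M) == dim(B$M)))
    stop("joint recurrence needs equal numbers of states")
  structure(list(M = A$M * B$M, mode = "joint", value = c(epsA, epsB),
                 radii = NULL, norm = norm, theiler = as.integer(theiler)),
            class = "recurrence_matrix")
}

#' Recurrence quantification measures
#'
#' Summary statistics of a recurrence matrix: recurrence rate (overall fill
#' rate), determinism `DET` (fraction of off-diagonal recurrence points on
#' diagonal lines of length at least `lmin`), laminarity `LAM` (fraction on
#' vertical lines of length at least `vmin`), recurrence period density
#' entropy `RPDE` (entropy of the vertical-gap period distribution,
#' normalized to `[0, 1]`; 0 for a single period, 1 for uniform), and the
#' generalized autocorrelation (mean recurrence per diagonal offset).
#'
#' @param rm a `recurrence_matrix` (square).
#' @param lmin,vmin minimum diagonal / vertical line lengths (default 2).
#' @param Tmin,Tmax recurrence-period range for RPDE (defaults 1 and
#'   `n - 1`).
#' @return An `rqa_measures` list with `recurrence_rate`, `det`, `lam`,
#'   `rpde`, and `gacf` (vector over offsets `0..n-1`).
#' @export
rqa_measures <- function(rm, lmin = 2, vmin = 2, Tmin = 1, Tmax = NULL) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  M <- rm$M
  n <- nrow(M)
  if (n != ncol(M)) stop("RQA measures need a square (auto) recurrence matrix")
  if (sum(M) == 0) stop("empty recurrence matrix: all measures undefined")
  if (is.null(Tmax)) Tmax <- n - 1L
  # diagonal lines (main diagonal excluded)
  dpts <- 0; dline <- 0
  for (dt in seq_len(n - 1L)) {
    v <- M[cbind(seq_len(n - dt), seq_len(n - dt) + dt)]
    dpts <- dpts + 2 * sum(v)
    r <- rle(v)
    dline <- dline + 2 * sum(r$lengths[r$values == 1 & r$lengths >= lmin])
  }
  det <- if (dpts > 0) dline / dpts else NA_real_
  # vertical lines (full matrix)
  vpts <- sum(M); vline <- 0
  for (j in seq_len(n)) {
    r <- rle(M[, j])
    vline <- vline + sum(r$lengths[r$values == 1 & r$lengths >= vmin])
  }
  lam <- vline / vpts
  # recurrence period density from vertical gaps (forward scan per column)
  gaps <- integer(0)
  for (j in seq_len(n)) {
    start <- j + rm$theiler + 1L
    if (start > n) next
    # the reference cell itself counts as recurrent, so a leading zero run
    # is a gap bounded by the (implicit) diagonal entry
    g <- vertical_gaps(c(1L, M[start:n, j]))
    gaps <- c(gaps, g)
  }
  gaps <- gaps[gaps >= Tmin & gaps <= Tmax]
  nT <- Tmax - Tmin + 1L
  if (length(gaps) == 0) {
    rpde <- NA_real_
  } else {
    p <- tabulate(gaps - Tmin + 1L, nbins = nT)
    p <- p / sum(p)
    p <- p[p > 0]
    rpde <- if (nT > 1) -sum(p * log(p)) / log(nT) else 0
  }
  gacf <- vapply(0:(n - 1L), function(dt) {
    mean(M[cbind(seq_len(n - dt), seq_len(n - dt) + dt)])
  }, numeric(1))
  structure(list(recurrence_rate = mean(M), det = det, lam = lam,
                 rpde = rpde, gacf = gacf, lmin = lmin, vmin = vmin),
            class = "rqa_measures")
}

# Lengths of zero runs strictly between ones in a binary vector whose first
# element is part of the initial sojourn block.
vertical_gaps <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  # zero runs flanked by ones on both sides, after the first one-block
  first_one <- which(r$values == 1)[1]
  if (is.na(first_one)) return(integer(0))
  out <- integer(0)
  for (i in seq_len(k)) {
    if (i > first_one && i < k && r$values[i] == 0 &&
        r$values[i - 1] == 1 && r$values[i + 1] == 1)
      out <- c(out, r$lengths[i])
  }
  out
}

#' @export
print.rqa_measures <- function(x, ...) {
  cat(sprintf("<rqa_measures> RR %.3f | DET %.3f (lmin %d) | LAM %.3f (vmin %d) | RPDE %.3f\n",
              x$recurrence_rate, x$det, x$lmin, x$lam, x$vmin, x$rpde))
  invisible(x)
}

#' Recurrence-time density
#'
#' For every reference state, the times at which the trajectory re-enters
#' the state's eps-neighborhood after having left it are collected as the
#' lengths of the non-recurrent gaps (equivalently: runs of vertical zeros
#' in the recurrence matrix, scanned forward in time from each reference).
#' The gap lengths are histogrammed at one-sample resolution over
#' `[Tmin, Tmax]` and normalized to a probability density. Recurrence
#' amplitudes are tracked alongside: for each recurrence, half the maximum
#' phase-space diameter of its excursion segment, averaged per period.
#'
#' @param ps `phase_space`.
#' @param eps radius in data units.
#' @param Tmin,Tmax period range in samples (defaults 1 and
#'   `floor(n/2)`).
#' @param theiler Theiler window (samples near the reference belong to its
#'   sojourn, not to a gap).
#' @param norm distance norm.
#' @return A `recurrence_density` list with `T`, `R` (counts), `P`
#'   (probabilities summing to 1 when any recurrence exists), `amplitude`
#'   (mean half-diameter per period, `NA` where no recurrence),
#'   `weighted_amplitude = amplitude * P`, and `empty` flag.
#' @export
recurrence_times <- function(ps, eps, Tmin = 1, Tmax = NULL, theiler = 0,
                             norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  states <- ps_states(ps)
  n <- nrow(states)
  if (is.null(Tmax)) Tmax <- floor(n / 2)
  Tmin <- as.integer(Tmin); Tmax <- as.integer(Tmax)
  stopifnot(Tmin >= 1, Tmax < n, Tmax >= Tmin, eps > 0)
  r <- rectimes_cpp(states, eps, Tmin, Tmax, as.integer(theiler),
                    norm == "maximum")
  R <- as.numeric(r$counts[, 1])
  tot <- sum(R)
  amp <- ifelse(R > 0, (r$ampsum[, 1] / pmax(R, 1)) / 2, NA_real_)
  structure(list(T = Tmin:Tmax, R = R,
                 P = if (tot > 0) R / tot else R,
                 amplitude = amp,
                 weighted_amplitude = ifelse(R > 0, amp * R / max(tot, 1), 0),
                 Tmin = Tmin, Tmax = Tmax, eps = eps, theiler = theiler,
                 empty = tot == 0),
            class = "recurrence_density")
}

#' @export
print.recurrence_density <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<recurrence_density> empty: no recurrences in [%d, %d]\n",
                x$Tmin, x$Tmax))
  } else {
    cat(sprintf("<recurrence_density> T in [%d, %d], %g recurrences, modal period %d\n",
                x$Tmin, x$Tmax, sum(x$R), x$T[which.max(x$P)]))
  }
  invisible(x)
}

#' Recurrence amplitude spectrum at a fixed radius
#'
#' Convenience wrapper around [recurrence_times()] exposing the amplitude
#' view: the mean half-diameter of the recurrent excursions per period and
#' the probability-weighted amplitude spectrum (rare long excursions with
#' large diameters are down-weighted by their recurrence probability). Raw
#' diameters are `2 * amplitude`.
#'
#' @inheritParams recurrence_times
#' @return A `recurrence_density` (see [recurrence_times()]).
#' @export
recurrence_amplitude <- function(ps, eps, Tmin = 1, Tmax = NULL, theiler = 0,
                                 norm = c("maximum", "euclidean")) {
  recurrence_times(ps, eps, Tmin = Tmin, Tmax = Tmax, theiler = theiler,
                   norm = norm)
}

#' Spatially-resolved recurrence period spectrum (SREPS)
#'
#' Recurrence-period probabilities as a function of the neighborhood size,
#' which is scanned over a grid expressed in percent of the standard
#' deviation of the analyzed series. Each radius column is normalized
#' separately, so the spectrum shows how the period estimate deforms with
#' scale: small radii are noise-dominated and uniform, very large radii
#' shift all mass toward short periods, and any oscillatory component forms
#' a continuous band whose best period estimate sits where the band meets
#' the small-radius noise regime.
#'
#' @param ts `nlts` or numeric vector.
#' @param dim,tau embedding parameters.
#' @param eps_sd_pct radius grid in percent of the series SD (default
#'   `1:100`).
#' @param Tmin,Tmax period range (defaults 1 and `floor(n/2)` capped at
#'   1000).
#' @param theiler Theiler window.
#' @param norm distance norm.
#' @return A `recurrence_spectrum` with `T`, `scale` (the percent grid),
#'   matrices `P`, `amplitude`, `weighted` (`T` rows x scale columns),
#'   `counts`, and `kind = "sreps"`.
#' @export
sreps <- function(ts, dim, tau, eps_sd_pct = 1:100, Tmin = 1, Tmax = NULL,
                  theiler = 0, norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  x <- ts_values(ts)
  ps <- delay_embed(x, dim, tau)
  n <- nrow(ps)
  if (is.null(Tmax)) Tmax <- min(floor(n / 2), 1000L)
  Tmin <- as.integer(Tmin); Tmax <- as.integer(Tmax)
  eps_abs <- eps_sd_pct / 100 * sd(x)
  r <- rectimes_cpp(ps_states(ps), eps_abs, Tmin, Tmax, as.integer(theiler),
                    norm == "maximum")
  build_spectrum(r, Tmin, Tmax, axis2 = eps_sd_pct, kind = "sreps",
                 fs = ts_fs(ts))
}

build_spectrum <- function(r, Tmin, Tmax, axis2, kind, fs = NULL) {
  counts <- r$counts
  tot <- colSums(counts)
  P <- sweep(counts, 2, pmax(tot, 1), `/`)
  amp <- ifelse(counts > 0, (r$ampsum / pmax(counts, 1)) / 2, NA_real_)
  W <- ifelse(counts > 0, amp * P, 0)
  structure(list(T = Tmin:Tmax, scale = axis2, P = P, amplitude = amp,
                 weighted = W, counts = counts, totals = tot,
                 Tmin = Tmin, Tmax = Tmax, kind = kind, fs = fs),
            class = "recurrence_spectrum")
}

#' Time-resolved recurrence amplitude spectrum (TRAS)
#'
#' Windowed recurrence-period analysis at a fixed neighborhood size: the
#' series is cut into overlapping windows (50% overlap by default), each
#' window is embedded and its recurrence-period density and
#' probability-weighted amplitudes computed. Because a recurrence only
#' requires states to return, the spectrum shows a single fundamental band
#' for non-sinusoidal oscillations where Fourier methods show harmonics.
#'
#' @param ts `nlts` or numeric vector.
#' @param dim,tau embedding parameters (applied per window).
#' @param eps_sd_pct radius in percent of the full-series SD (default 20).
#' @param window_len window length in samples (default `N/10`).
#' @param overlap fractional window overlap in `[0, 1)` (default 0.5).
#' @param Tmin,Tmax period range (default `Tmax` = half the states per
#'   window).
#' @param theiler Theiler window.
#' @param norm distance norm.
#' @return A `recurrence_spectrum` with `scale` holding the window start
#'   sample (1-based) and `kind = "tras"`.
#' @export
tras <- function(ts, dim, tau, eps_sd_pct = 20, window_len = NULL,
                 overlap = 0.5, Tmin = 1, Tmax = NULL, theiler = 0,
                 norm = c("maximum", "euclidean")) {
  norm <- match.arg(norm)
  x <- ts_values(ts)
  N <- length(x)
  if (is.null(window_len)) window_len <- floor(N / 10)
  window_len <- as.integer(window_len)
  stopifnot(window_len <= N, overlap >= 0, overlap < 1)
  need <- (dim - 1L) * tau + 2L
  if (window_len < need)
    stop(sprintf("window too short to embed: need >= %d samples", need))
  hop <- max(1L, as.integer(round(window_len * (1 - overlap))))
  nwin <- floor((N - window_len) / hop) + 1L
  states_per_win <- window_len - (dim - 1L) * tau
  if (is.null(Tmax)) Tmax <- floor(states_per_win / 2)
  Tmin <- as.integer(Tmin); Tmax <- as.integer(Tmax)
  if (Tmax >= states_per_win)
    stop("'Tmax' must be below the number of states per window")
  eps_abs <- eps_sd_pct / 100 * sd(x)
  tlen <- Tmax - Tmin + 1L
  counts <- matrix(0, tlen, nwin)
  ampsum <- matrix(0, tlen, nwin)
  starts <- (seq_len(nwin) - 1L) * hop + 1L
  for (w in seq_len(nwin)) {
    seg <- x[starts[w]:(starts[w] + window_len - 1L)]
    ps <- delay_embed(seg, dim, tau)
    r <- rectimes_cpp(ps_states(ps), eps_abs, Tmin, Tmax, as.integer(theiler),
                      norm == "maximum")
    counts[, w] <- r$counts[, 1]
    ampsum[, w] <- r$ampsum[, 1]
  }
  sp <- build_spectrum(list(counts = counts, ampsum = ampsum), Tmin, Tmax,
                       axis2 = starts, kind = "tras", fs = ts_fs(ts))
  sp$window_len <- window_len
  sp$hop <- hop
  sp$eps_sd_pct <- eps_sd_pct
  sp
}

#' @export
print.recurrence_spectrum <- function(x, ...) {
  cat(sprintf("<recurrence_spectrum> %s: T in [%d, %d] x %d %s columns; total recurrences %g\n",
              toupper(x$kind), x$Tmin, x$Tmax, length(x$scale),
              if (x$kind == "sreps") "radius" else "window",
              sum(x$totals)))
  invisible(x)
}

#' @export
plot.recurrence_spectrum <- function(x, what = c("P", "weighted"), ...) {
  what <- match.arg(what)
  z <- x[[what]]
  graphics::image(x$scale, x$T, t(z),
                  xlab = if (x$kind == "sreps") "radius (% SD)" else "window start (sample)",
                  ylab = "recurrence period T (samples)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Fundamental recurrence period of a spatially-resolved spectrum
#'
#' Reads the best period estimate off an SREPS: the fundamental period of
#' the continuous oscillatory band at the radius where the band meets the
#' small-radius regime. The band is tracked from the largest usable radius
#' toward smaller ones — a column is usable when it holds at least
#' `min_total` recurrences and its modal probability exceeds `peak_factor`
#' times the uniform level, and the band continues while the modal period
#' of adjacent columns changes by at most `band_tol` samples. Below the
#' crossing the modal period jumps (tiny neighborhoods are missed for
#' several cycles, so mass sits at higher multiples of the true period, or
#' is noise-dominated). At the crossing column the fundamental is the
#' smallest local maximum of `P(T)` reaching at least half the modal
#' probability, so harmonic peaks at multiples are ignored.
#'
#' @param spectrum a `recurrence_spectrum` of kind `"sreps"`.
#' @param min_total minimum recurrences for a column to be evaluated.
#' @param peak_factor modal-probability threshold relative to uniform.
#' @param band_tol maximum modal-period step (samples) between adjacent
#'   columns of the same band.
#' @return List with `period` (samples), `scale` (the crossing radius, in
#'   the spectrum's scale units), `peaks` (all detected peak periods at the
#'   crossing) and `band` (the modal period per scale over the tracked
#'   band, `NA` outside it).
#' @export
fundamental_period <- function(spectrum, min_total = 100, peak_factor = 5,
                               band_tol = 2) {
  stopifnot(inherits(spectrum, "recurrence_spectrum"))
  P <- spectrum$P
  nT <- length(spectrum$T)
  unif <- 1 / nT
  maxP <- apply(P, 2, max)
  valid <- spectrum$totals >= min_total & maxP >= peak_factor * unif
  if (!any(valid))
    return(list(period = NA_real_, scale = NA_real_, peaks = numeric(0),
                band = rep(NA_real_, length(spectrum$scale))))
  modal <- spectrum$T[apply(P, 2, which.max)]
  e <- max(which(valid))
  while (e > 1 && valid[e - 1] && abs(modal[e - 1] - modal[e]) <= band_tol)
    e <- e - 1L
  cross <- e
  band <- rep(NA_real_, length(spectrum$scale))
  band[cross:max(which(valid))] <- modal[cross:max(which(valid))]
  p <- P[, cross]
  pk <- local_maxima(p)
  pk <- pk[p[pk] >= 0.5 * max(p)]
  list(period = spectrum$T[pk[1]], scale = spectrum$scale[cross],
       peaks = spectrum$T[pk], band = band)
}

# Indices of strict-or-plateau local maxima of a nonnegative vector,
# with a 1-sample neighborhood.
local_maxima <- function(p) {
  n <- length(p)
  if (n < 3) return(which.max(p))
  idx <- which(p[2:(n - 1)] >= p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n] &
                 p[2:(n - 1)] > 0) + 1L
  if (p[1] > p[2]) idx <- c(1L, idx)
  if (p[n] > p[n - 1]) idx <- c(idx, n)
  if (length(idx) == 0) idx <- which.max(p)
  idx
}
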