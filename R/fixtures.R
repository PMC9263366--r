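#' Simulate the Lorenz system
#'
#' Integrates the three-variable Lorenz convection model
#' \deqn{\dot X = a (Y - X),\quad \dot Y = X (b - Z) - Y,\quad \dot Z = X Y - c Z}
#' with fixed-step fourth-order Runge-Kutta at an internal step of
#' `1/(10 fs)`, subsampled to the requested rate. The canonical chaotic
#' parameters are `a = 10`, `b = 28`, `c = 8/3`. A transient (default 10 s)
#' is integrated and discarded before recording so that the trajectory has
#' settled on the attractor regardless of the initial condition. When
#' `initial_state` is `NULL` it is drawn uniformly from `[-10, 10]^3` using
#' the seeded generator.
#'
#' @param a,b,c dimensionless Lorenz parameters.
#' @param fs sampling rate (Hz).
#' @param duration recorded duration (s); the output has `duration * fs`
#'   samples.
#' @param initial_state numeric length-3 start state, or `NULL` to draw one.
#' @param seed integer seed for the initial condition draw (ignored when
#'   `initial_state` is given).
#' @param transient seconds integrated and discarded before recording.
#' @return List with `x` (an [nlts] with the X component), `trajectory`
#'   (matrix with columns X, Y, Z) and `fs`.
#' @examples
#' lo <- lorenz_series(duration = 5, fs = 40, seed = 1)
#' lo$x
#' @export
lorenz_series <- function(a = 10, b = 28, c = 8 / 3, fs = 40, duration = 250,
                          initial_state = NULL, seed = NULL, transient = 10) {
  stopifnot(fs > 0, duration > 0, transient >= 0)
  if (is.null(initial_state)) {
    initial_state <- with_seed(seed, runif(3, -10, 10))
  }
  stopifnot(length(initial_state) == 3, all(is.finite(initial_state)))
  deriv <- function(t, y, p) {
    list(c(p$a * (y[2] - y[1]),
           y[1] * (p$b - y[3]) - y[2],
           y[1] * y[2] - p$c * y[3]))
  }
  h <- 1 / (10 * fs)
  times <- seq(0, transient + duration, by = h)
  sol <- deSolve::ode(y = c(X = initial_state[1], Y = initial_state[2],
                            Z = initial_state[3]),
                      times = times, func = deriv,
                      parms = list(a = a, b = b, c = c), method = "rk4")
  if (any(!is.finite(sol[, -1])))
    stop("Lorenz integration diverged (non-finite state); check parameters")
  # subsample to fs, drop the transient, keep duration*fs samples
  keep <- seq(1L, nrow(sol), by = 10L)
  sol <- sol[keep, , drop = FALSE]
  first <- round(transient * fs) + 1L
  idx <- first:(first + round(duration * fs) - 1L)
  traj <- unname(sol[idx, c("X", "Y", "Z"), drop = FALSE])
  colnames(traj) <- c("X", "Y", "Z")
  list(x = nlts(traj[, "X"], fs = fs, label = "lorenz_X"),
       trajectory = traj, fs = fs)
}

# Right-hand side of the Lorenz equations (used by tests for the fixed point).
lorenz_deriv <- function(state, a = 10, b = 28, c = 8 / 3) {
  c(a * (state[2] - state[1]),
    state[1] * (b - state[3]) - state[2],
    state[1] * state[2] - c * state[3])
}

#' Iterate the logistic map
#'
#' Generates `n` iterates of \eqn{x_{n+1} = a x_n (1 - x_n)}. For
#' `0 < a <= 4` and `x0` in (0,1) the orbit stays in (0,1); `a = 3.92`
#' produces chaotic dynamics, `a = 4` the fully chaotic map with invariant
#' arcsine density and Lyapunov exponent `ln 2`.
#'
#' @param a control parameter, `0 < a <= 4`.
#' @param x0 initial value in (0,1), or `NULL` to draw one uniformly with
#'   `seed`.
#' @param n number of iterates returned (excluding `x0`).
#' @param seed integer seed for the initial-condition draw.
#' @return An [nlts] with the `n` iterates `x_1, ..., x_n`.
#' @examples
#' logistic_series(a = 3.92, x0 = 0.5, n = 5)$values
#' @export
logistic_series <- function(a = 3.92, x0 = NULL, n = 100, seed = NULL) {
  stopifnot(a > 0, a <= 4, n >= 1)
  if (is.null(x0)) x0 <- with_seed(seed, runif(1, 0.05, 0.95))
  if (x0 <= 0 || x0 >= 1) stop("'x0' must lie strictly inside (0, 1)")
  x <- numeric(n)
  cur <- x0
  for (i in seq_len(n)) {
    cur <- a * cur * (1 - cur)
    x[i] <- cur
  }
  nlts(x, fs = NULL, label = sprintf("logistic_a%.3g", a))
}

#' Correlated Gaussian pair
#'
#' Draws `n` samples from a bivariate normal with standard deviations
#' `sigma_x`, `sigma_y` and covariance `cov`. The degenerate perfectly
#' correlated case (`|cov| = sigma_x * sigma_y`) is generated as an exact
#' linear copy.
#'
#' @param n number of samples.
#' @param sigma_x,sigma_y marginal standard deviations.
#' @param cov covariance, with `|cov| <= sigma_x * sigma_y`.
#' @param seed integer seed.
#' @return List with [nlts] components `x` and `y`.
#' @export
gaussian_pair <- function(n, sigma_x = 1, sigma_y = 1, cov = 0.9, seed = NULL) {
  stopifnot(n >= 2, sigma_x > 0, sigma_y > 0)
  if (abs(cov) > sigma_x * sigma_y + 1e-12)
    stop("|cov| must not exceed sigma_x * sigma_y")
  if (abs(abs(cov) - sigma_x * sigma_y) < 1e-12) {
    x <- with_seed(seed, rnorm(n, sd = sigma_x))
    y <- sign(cov) * (sigma_y / sigma_x) * x
  } else {
    S <- matrix(c(sigma_x^2, cov, cov, sigma_y^2), 2, 2)
    xy <- with_seed(seed, MASS::mvrnorm(n, mu = c(0, 0), Sigma = S))
    x <- xy[, 1]
    y <- xy[, 2]
  }
  list(x = nlts(x, label = "gauss_x"), y = nlts(y, label = "gauss_y"))
}

#' Compound oscillation with selectable waveform segments
#'
#' Concatenates equally long segments of a sine, sawtooth and/or square wave
#' of a common fundamental frequency, optionally adding white Gaussian noise
#' scaled to a fraction of the raw signal's standard deviation. Used to probe
#' recurrence-period spectra: all three waveforms share the same fundamental
#' period, but Fourier methods show harmonics for the non-sinusoidal
#' segments.
#'
#' @param freq fundamental frequency (Hz).
#' @param fs sampling rate (Hz), must exceed `2 * freq`.
#' @param segment_duration duration of each segment (s).
#' @param shapes character vector drawn from `"sine"`, `"sawtooth"`,
#'   `"square"`, in segment order.
#' @param amplitude peak amplitude of each waveform.
#' @param noise_frac standard deviation of the added Gaussian noise as a
#'   fraction of the noise-free signal's SD (0 disables noise).
#' @param seed integer seed for the noise draw.
#' @return An [nlts] of length `fs * segment_duration * length(shapes)`.
#' @examples
#' sig <- compound_oscillation(33, 1000, 0.2, c("sine", "square"))
#' @export
compound_oscillation <- function(freq, fs, segment_duration,
                                 shapes = c("sine", "sawtooth", "square"),
                                 amplitude = 1, noise_frac = 0, seed = NULL) {
  stopifnot(fs > 2 * freq, segment_duration > 0, noise_frac >= 0)
  shapes <- match.arg(shapes, c("sine", "sawtooth", "square"),
                      several.ok = TRUE)
  nseg <- round(segment_duration * fs)
  waveform <- function(shape, t) {
    ph <- freq * t
    switch(shape,
      sine = sin(2 * pi * ph),
      # rising ramp from -1 to 1 each cycle
      sawtooth = 2 * (ph - floor(ph)) - 1,
      square = ifelse(ph - floor(ph) < 0.5, 1, -1))
  }
  segs <- lapply(seq_along(shapes), function(i) {
    t <- (seq_len(nseg) - 1) / fs
    amplitude * waveform(shapes[i], t)
  })
  x <- unlist(segs)
  if (noise_frac > 0) {
    x <- x + with_seed(seed, rnorm(length(x), sd = noise_frac * sd(x)))
  }
  nlts(x, fs = fs, label = paste(shapes, collapse = "+"))
}
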