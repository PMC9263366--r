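# Shared benchmark objects, computed once per test run.
.bench <- new.env(parent = emptyenv())

bench_lorenz <- function() {
  if (is.null(.bench$lorenz))
    .bench$lorenz <- lorenz_series(duration = 250, fs = 40, seed = 42)
  .bench$lorenz
}

bench_lorenz_tau <- function() {
  if (is.null(.bench$tau)) {
    ami <- auto_mutual_information(bench_lorenz()$x, max_lag = 50)
    .bench$ami <- ami
    .bench$tau <- ami$first_minimum
  }
  .bench$tau
}

bench_lorenz_ami <- function() {
  bench_lorenz_tau()
  .bench$ami
}

bench_lorenz_ps <- function() {
  if (is.null(.bench$ps))
    .bench$ps <- delay_embed(bench_lorenz()$x, 3, bench_lorenz_tau())
  .bench$ps
}

# AR(1) generator used by several tests
gen_ar1 <- function(n, phi = 0.8, seed = 1) {
  withr::with_seed(seed, {
    x <- numeric(n)
    for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1)
    x
  })
}

# Brute-force max-norm distance between two state rows
brute_dist <- function(A, i, j, norm = "maximum") {
  d <- abs(A[i, ] - A[j, ])
  if (norm == "maximum") max(d) else sqrt(sum(d^2))
}
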