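---
title: "Nonlinear time-series methods in nltsa: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear time-series methods in nltsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nltsa)
```

`nltsa` analyzes sampled signals under the working assumption that they were
produced by a nonlinear dynamical system observed through a scalar
measurement. Three method families are covered: dynamical-systems estimators
(embedding, correlation dimension, Lyapunov exponents, unstable periodic
orbits), recurrence quantification (recurrence matrices, recurrence-time
densities and the spatially- and time-resolved recurrence period/amplitude
spectra), and information theory (entropy, mutual information, active
information storage). Surrogate ensembles and nonparametric permutation
tests supply the statistics. This vignette records the models, the
conventions, and every numerical decision that was genuinely open, so that
results are interpretable without reading the source.

## Phase-space reconstruction

A scalar series $x_t$ sampled at rate $f_s$ is embedded by time-delay
coordinates,
$$\mathbf{x}_t = (x_{t-(d-1)\tau},\ \dots,\ x_{t-\tau},\ x_t),$$
with dimension $d$ and delay $\tau$ in samples. `delay_embed()` uses this
*backward* convention: a state's index is the index of its newest
coordinate, so a prediction at horizon $h$ targets sample $t+h$. Columns
are ordered oldest to newest. Distances default to the maximum norm
throughout (the Euclidean norm is selectable everywhere); all radii are in
the units of the data unless explicitly expressed in percent of the
standard deviation.

Neighbor statistics exclude temporally close pairs through a Theiler window
$w$: pairs with $|i-j|\le w$ never count. The default scale for $w$ is
twice the autocorrelation time, defined as the first zero crossing of the
autocorrelation function (`autocorrelation_time()`; if no crossing occurs
within $N/2$ lags, $N/10$ is used). `space_time_separation()` offers the
empirical alternative: the suggested window is the first temporal
separation at which the median spatial-separation curve flattens (slope
over a 5-sample window below 1% of the attractor diameter per sample — a
rule we fixed because the plateau is otherwise judged by eye).

### Choosing the embedding parameters

The deterministic pathway picks $\tau$ at the first strict local minimum of
the auto-mutual information and $d$ from the false-nearest-neighbor curve.
The FNN criterion is Kennel's: the nearest neighbor of each state at
dimension $d$ is false when the distance gained by the coordinate added at
$d+1$ exceeds `Rtol` (default 10) times the dimension-$d$ distance, or when
the dimension-$(d+1)$ distance exceeds `Atol` (default 2) standard
deviations. One convention matters more than it looks: the added
coordinate extends the state *forward* in time. On dissipative attractors
the contracting rate is much larger in magnitude than the expanding one
(for the canonical Lorenz flow, $-14.6$ vs $+0.9\,s^{-1}$), so a backward
extension blows up the separation of genuinely close neighbors along the
stable direction and misclassifies them — on Lorenz data roughly one point
in ten. "Drops to zero" is operationalized as an FNN fraction below 1%
(configurable `drop`).

The stochastic pathway (`ragwitz_optimize()`) scans a $(d,\tau)$ grid with
a local-constant predictor: each state's next sample is predicted by the
mean successor of its $k$ nearest neighbors (default $k=30$), and the grid
cell minimizing the root-mean-square prediction error wins. Because
neighboring cells of the grid often differ by less than the Monte-Carlo
error of the RMSPE itself, cells within 1% of the minimum are treated as
tied and the smallest dimension, then the smallest delay, is selected —
parsimony decides statistical ties. For a first-order autoregression this
reliably returns $d=1$, which the strict argmin does not.

## Dynamic invariants

**Correlation dimension.** `correlation_sum()` counts Theiler-admissible
state pairs closer than $\varepsilon$ over a radius grid (default: 40
log-spaced radii spanning 1–100% of the attractor diameter), normalized so
that $C(\varepsilon)\to 1$ at the diameter. $D_2$ is the least-squares
slope of $\log C$ vs $\log\varepsilon$ inside a scaling region. When no
fit range is given, `propose_fit_range()` selects the longest contiguous
run of stable local slopes (sliding-window slopes within 15% of the run's
median), after dropping radii supported by fewer than 10 pairs.

**Largest Lyapunov exponent.** Both classic neighbor-divergence algorithms
are implemented: Kantz (log of the mean distance over all neighbors within
$\varepsilon$) and Rosenstein (single nearest neighbor). Neighborhoods are
found in full state space, but the propagated distance is measured on the
newest scalar coordinate only (Kantz's own convention); measuring it on the
full delay vector smears the divergence over the $(d-1)\tau$-sample window.
Two features of these curves drive the default fit range in
`lyapunov_fit()`. First, the early iterations underestimate nothing — they
*overestimate*: neighbor pairs must first rotate into the locally most
expanding direction, and until they do, the mean log distance grows at a
mixture of rates that exceeds the largest exponent (on the 40-Hz Lorenz
benchmark this alignment transient lasts about two orbital periods).
Second, once distances approach the attractor scale the curve flattens and
any fit through that region is biased toward zero. The default therefore
computes the saturation level as the log mean distance of temporally
unrelated state pairs, discards iterations within 0.5 log units of it, and
fits the *later half* of what remains. For the Lorenz benchmark we track
120 iterations with a Kantz neighborhood of 0.3% of the attractor diameter
— about twice the median nearest-neighbor spacing, i.e. the nearest-neighbor
limit in which the two algorithms are expected to coincide; with the
common textbook setting of 5% of the diameter the initial separations are
within two log units of saturation and no scaling region survives at this
sampling rate.

**Unstable periodic orbits.** `upo_transform()` detects period-one orbits
of a map from its return plane $(x_n, x_{n+1})$. The local slope $s_n$ at
each point is a least-squares fit over its $k=10$ nearest neighbors'
successor pairs; each repetition perturbs it to
$s_n + r\,(x_{n+1}-x_n)$ with $r\sim U[-\kappa,\kappa]$ and maps the point
to the fixed point of its local linearization,
$x^\ast = (x_{n+1}-s_n x_n)/(1-s_n)$ (points with $|1-s_n|$ below $10^{-8}$
are skipped for that repetition). Points on the diagonal are insensitive
to the perturbation because the factor $x_{n+1}-x_n$ vanishes there, so
over repetitions true fixed points accumulate while unrelated points
scatter. The perturbation scale is the one genuinely free knob: with
$\kappa \lesssim 0.4/\mathrm{SD}(x)$ the dispersal is too weak and
spurious side-modes survive near the density maximum of the orbit itself;
the default $\kappa = 0.5/\mathrm{SD}(x)$ (units of 1/data, making the
perturbation a dimensionless slope) disperses them while leaving the
diagonal fixed points untouched. The accumulated histogram (100 bins over
the data range) is normalized to unit mass; significance of its peak is
assessed by a surrogate Z test on the peak height (`upo_significance()`).

**Detrended fluctuation analysis.** Standard DFA: integrate the centered
series, detrend per non-overlapping window with a polynomial of order
`order` (default linear), and fit the log-log slope of the RMS fluctuation
over 12 log-spaced scales between `order + 2` (at least 4) and $N/4$.

## Recurrence analysis

`recurrence_matrix()` thresholds pairwise state distances at a fixed radius
(symmetric matrix) or adjusts a per-state radius to hit a target
recurrence rate (the distance to the $\lceil \mathrm{rate}\cdot
n_\mathrm{adm}\rceil$-th admissible neighbor). RQA summaries follow the
standard line-based definitions: determinism is the fraction of
off-main-diagonal recurrence points on diagonal lines of length $\ge
l_{\min}$ (default 2), laminarity the vertical-line analogue, the
generalized autocorrelation the mean recurrence per diagonal offset, and
the recurrence period density entropy the Shannon entropy of the
recurrence-time distribution normalized by $\log$ of the number of
admissible periods.

**Recurrence times.** The recurrence time of a reference state is the
length of the run of non-recurrent samples between leaving and re-entering
its $\varepsilon$-neighborhood, scanned forward in time; samples inside
the Theiler window belong to the initial sojourn, and the reference cell
itself counts as recurrent, so a leading zero run is a valid gap. This
column-wise bookkeeping never materializes the $n\times n$ matrix (memory
stays linear in $n$ per radius), and its equivalence to counting vertical
zero runs in the explicit matrix is enforced by a test. Gap lengths are
histogrammed at one-sample resolution over $[T_{\min}, T_{\max}]$ and
normalized per radius.

**Amplitudes.** Each recurrence's excursion segment (the gap samples plus
the bounding recurrent samples) has a phase-space diameter, computed from
per-coordinate extremes — exact under the maximum norm, a bounding-box
diagonal under the Euclidean norm. Reported amplitudes are *half* this
diameter, so a sinusoid of amplitude $a$, embedded at a quarter-period
delay, reports $\approx a$ at its period; raw diameters are twice the
reported value. Spectra also carry the probability-weighted amplitude
$\bar a(T)\,P(T)$, which suppresses rare long excursions with large
diameters.

**SREPS and TRAS.** The spatially-resolved spectrum computes $P(T,
\varepsilon)$ over a radius grid in percent of the SD of the analyzed
series (default 1–100% in steps of 1); the time-resolved spectrum computes
$P(T, w)$ in overlapping windows (default length $N/10$, 50% overlap) at a
fixed radius (default 20% SD). Three regimes structure an SREPS: tiny
radii are either noise-dominated or, for clean oscillations, concentrate
mass at *multiples* of the true period (the trajectory misses a small
neighborhood for several cycles before re-entering); very large radii
swallow adjacent samples and push mass toward short periods; in between,
an oscillatory component forms a continuous band that drifts slowly toward
smaller $T$ as the radius grows. `fundamental_period()` operationalizes
the reading rule "take the band where it meets the small-radius regime":
it tracks the modal period from the largest usable radius downward (a
column is usable with at least 100 recurrences and a modal probability at
least 5 times the uniform level) while adjacent modal periods differ by at
most 2 samples, calls the smallest such radius the crossing, and reports
the smallest peak there that reaches half the modal probability — so
harmonic peaks at multiples are never mistaken for the fundamental.
Because recurrences only require states to return, non-sinusoidal
waveforms (sawtooth, square) produce a single fundamental band where
Fourier spectra show harmonics.

## Information theory

All information quantities are in bits. The binned estimators use
equal-width bins over the observed range, with the Freedman–Diaconis rule
(width $2\,\mathrm{IQR}\,n^{-1/3}$) as the automatic bin count; when the
IQR is degenerate a Sturges-like fallback applies with a warning. Binned
Shannon entropy is reported both raw and with the $+\log_2(\text{bin
width})$ correction that makes it comparable to differential entropy. The
nearest-neighbor estimators are Kozachenko–Leonenko for differential
entropy and Kraskov–Stögbauer–Grassberger (algorithm 1, max-norm strict
counting, default mass 4) for mutual information. Duplicate points make a
$k$-th neighbor distance zero; the default policy breaks such ties with a
deterministic seeded jitter ten orders of magnitude below the data range,
and an error policy is available. Active information storage is the
mutual information between the embedded past state and the next sample.
Every estimator returns local (per-sample) values whose mean equals the
global estimate by construction; this identity is tested to $10^{-10}$.

Known estimator behaviors to keep in mind: the binned mutual information
drifts upward as the bin count grows (finite-sample bias
$\sim (B-1)^2/2N\ln 2$), and the KSG estimator underestimates for masses
in the hundreds. Tests pin both trends.

## Surrogates and statistics

Shuffle and block-shuffle surrogates permute values or blocks (default
block length: the autocorrelation time). Phase-randomized (`ft`)
surrogates draw Hermitian-symmetric random phases, preserving the
amplitude spectrum to rounding. Amplitude-adjusted (`aaft`) surrogates
iterate rank-remapping onto the original value multiset against restoring
the original amplitude spectrum, stopping when the relative spectral
discrepancy changes by less than $10^{-4}$ or after 100 iterations, and
always end on the rank step — the value distribution is conserved
*exactly*, the spectrum approximately.

The time-reversal statistic $Q(\Delta t) = \langle (x_t -
x_{t-\Delta t})^3\rangle$ feeds a two-sided surrogate Z test
($Z = (Q_\mathrm{obs} - \bar Q_\mathrm{surr})/\mathrm{SD}(Q_\mathrm{surr})$,
rejection when $|Z| > 1.96$ at the 5% level). The test has low power for
signals whose scalar marginal is nearly time-reversible: the Lorenz X
component is a case in point — its $Q$ at unit lag sits well inside the
AAFT surrogate distribution even for long records, while strongly
asymmetric waveforms (sawtooth) or the Lorenz Z component reject
overwhelmingly. Group comparisons use the Monte-Carlo permutation test
(two-sided, with the $+1$ correction so $p \in (0,1]$) and the
cluster-based permutation test for trials-by-samples data, whose default
pointwise threshold is the 97.5th percentile of the permutation
distribution of the pointwise $|t|$, with cluster mass the sum of $|t|$
and familywise control through the max-cluster-mass null.

## The synthetic generators as study conditions

The validation suite runs entirely on generated data; the generators'
defaults are the study conditions, not tuning knobs:

* **Lorenz flow** ($\dot X = a(Y-X)$, $\dot Y = X(b-Z)-Y$, $\dot Z = XY -
  cZ$; $a=10$, $b=28$, $c=8/3$): fixed-step RK4 at $1/(10 f_s)$,
  subsampled to $f_s = 40$ Hz, 250 s recorded after a 10-s transient from
  an initial condition drawn uniformly in $[-10,10]^3$. The fixed-step
  integrator makes runs bit-reproducible for a given seed; step halving
  changes $X(t)$ by less than $10^{-6}$ over 10 s.
* **Logistic map** $x_{n+1} = a x_n (1-x_n)$: chaotic at $a=3.92$ (UPO
  benchmark, 100 iterates), fully chaotic at $a=4$ (arcsine invariant
  density, $\lambda = \ln 2$).
* **Correlated Gaussian pair**: unit variances, covariance 0.9 (analytic
  entropy $\tfrac12\log_2 2\pi e \approx 2.047$ bits, mutual information
  $-\tfrac12\log_2(1-0.81) \approx 1.198$ bits).
* **Compound oscillation**: concatenated sine/sawtooth/square segments of
  a common fundamental (33 Hz at 1 kHz for the harmonic-free TRAS
  demonstration; 3 Hz at 100 Hz with additive Gaussian noise at 8% of the
  raw SD for the SREPS noise-crossing benchmark).

What these generators do *not* emulate — measurement noise on the Lorenz
and logistic data, nonstationarity beyond concatenated segments,
trial-to-trial variability, line noise, artifacts — bounds what passing
tests show: they validate the estimators' correctness and calibration on
clean, stationary, well-sampled signals, not robustness to the full mess
of experimental recordings. The preprocessing chain (windowing, linear
detrending, zero-phase Butterworth filtering via forward–backward
application, z-scoring, applied in that fixed order with normalization
last so that percent-of-SD radii refer to the analyzed series) is the
intended first line of defense on real data.

## Problem sizes, degenerate inputs, limitations

The shipped tests and the reproduction script use 10,000-sample Lorenz
records, 5,000–10,000-sample noise and map series, 100-iterate logistic
orbits, ensembles of 100–1,000 surrogates, and 100–500 Monte-Carlo
repetitions — sizes at which every benchmark statistic is stable across
seeds.

Degenerate inputs fail loudly rather than silently: constant series are
rejected by the entropy, AMI, FNN, DFA and z-scoring routines (zero range
or zero SD); empty neighborhoods are reported, not fatal, in prediction
and Lyapunov estimation (queries are skipped and counted) but abort the
computation when *no* reference survives; rate-mode recurrence rejects
rates below $1/(n-1)$; surrogate tests abort on zero surrogate variance.

Known limitations: exponents and dimensions inherit the usual
finite-sample biases of neighbor methods (the Lyapunov fit is only as good
as its scaling region, which the saturation-aware default locates but
cannot conjure when the record is short or the neighborhood too large);
recurrence amplitudes under the Euclidean norm use a bounding-box
surrogate for the true segment diameter; the UPO routine detects
period-one orbits of maps only; and the time-reversal test's power depends
strongly on which observable of a system is measured.
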