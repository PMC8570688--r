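#' Thalamic input parameters for one contrast level
#'
#' The external drive to every neuron is the rectified rate
#' `nu(t) = [S(K,t) + A(K,t) * eps_gamma(t) + theta_n * n(t)]_+` where
#' `eps_gamma` is unit-variance ~57 Hz band-limited noise, `n` is z-scored
#' 1/f^1.5 colored noise, and the reversal-locked envelopes are
#' `A(K,t) = A0(K) - alpha(K) f(t - t* - Dt)` and
#' `S(K,t) = S0(K) + beta(K) f(t - t*)` (see [reversal_envelope]).
#'
#' @param K contrast level (%); if it matches a row of the shipped parameter
#'   table (see [thalamic_table]) the remaining defaults come from that row.
#' @param A0,alpha baseline and reversal-driven modulation amplitude of the
#'   periodic component (sp/s); `alpha <= A0`.
#' @param S0,beta baseline and reversal-driven modulation amplitude of the
#'   sustained component (sp/s).
#' @param osc_center,osc_bandwidth center (default 57 Hz) and bandwidth
#'   (default 10 Hz) of the periodic component.
#' @param noise_amplitude colored-noise amplitude theta_n (sp/ms; default
#'   0.4, i.e. 400 sp/s per unit SD).
#' @param noise_exponent spectral exponent of the colored noise (default 1.5).
#' @param reversal_times grating contrast-reversal times (s); empty for
#'   time-invariant input.
#' @param latency_Dt latency of the periodic-envelope modulation relative to
#'   the sustained one (ms; default 40).
#' @return object of class `thalamic_input_params`.
#' @export
#' @examples
#' thalamic_input_params(K = 0)    # A0 = 40, S0 = 500 from the table
#' thalamic_input_params(K = 90, reversal_times = c(1, 1.5))
thalamic_input_params <- function(K, A0 = NULL, alpha = NULL, S0 = NULL,
                                  beta = NULL, osc_center = 57,
                                  osc_bandwidth = 10, noise_amplitude = 0.4,
                                  noise_exponent = 1.5,
                                  reversal_times = numeric(0),
                                  latency_Dt = 40) {
  tab <- thalamic_table()
  row <- if (length(K) == 1 && !is.na(K)) tab[tab$K == K, , drop = FALSE]
         else tab[0, , drop = FALSE]
  if (nrow(row) == 1) {
    if (is.null(A0)) A0 <- row$A0
    if (is.null(alpha)) alpha <- row$alpha
    if (is.null(S0)) S0 <- row$S0
    if (is.null(beta)) beta <- row$beta
  } else if (is.null(A0) || is.null(alpha) || is.null(S0) || is.null(beta)) {
    stop("contrast K not in the parameter table; supply A0, alpha, S0, beta",
         call. = FALSE)
  }
  if (any(c(A0, alpha, S0, beta) < 0))
    stop("invalid configuration: rate amplitudes must be non-negative",
         call. = FALSE)
  if (alpha > A0 + 1e-12)
    stop("invalid configuration: alpha must not exceed A0", call. = FALSE)
  if (is.unsorted(reversal_times))
    stop("invalid configuration: reversal_times must be sorted", call. = FALSE)
  structure(list(K = K, A0 = A0, alpha = alpha, S0 = S0, beta = beta,
                 osc_center = osc_center, osc_bandwidth = osc_bandwidth,
                 noise_amplitude = noise_amplitude,
                 noise_exponent = noise_exponent,
                 reversal_times = reversal_times, latency_Dt = latency_Dt),
            class = "thalamic_input_params")
}

#' Per-contrast thalamic parameter table
#'
#' Time-invariant amplitudes `A(K)`, `S(K)` and time-dependent parameters
#' `A0, alpha, S0, beta` for the six contrast levels 0, 10, 20, 30, 50, 90.
#'
#' @return data.frame with columns K, A, S, A0, alpha, S0, beta (sp/s).
#' @export
thalamic_table <- function() {
  read.csv(system.file("extdata", "thalamic_input_table.csv",
                       package = "v1gamma"))
}

#' Band-limited gamma noise
#'
#' Gaussian white noise passed through a causal third-order bandpass
#' Butterworth filter (center 57 Hz, bandwidth 10 Hz by default) and scaled
#' to unit variance, so the amplitude parameter `A` alone sets the strength
#' of the periodic input component.
#'
#' @param duration length (s).
#' @param dt sample step (ms).
#' @param center,bandwidth passband center and width (Hz).
#' @param seed optional integer seed.
#' @return numeric vector of length `duration*1000/dt`, unit variance.
#' @export
gamma_filtered_noise <- function(duration, dt = 0.05, center = 57,
                                 bandwidth = 10, seed = NULL) {
  fs <- 1000 / dt
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (lo <= 0) stop("invalid configuration: passband reaches 0 Hz", call. = FALSE)
  if (hi >= fs / 2)
    stop("invalid configuration: passband exceeds the Nyquist frequency",
         call. = FALSE)
  if (duration < 1 / bandwidth)
    stop("duration too short to resolve the passband", call. = FALSE)
  n <- round(duration * 1000 / dt)
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
  }
  w <- rnorm(n)
  bf <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, w))  # causal, forward-only
  x / sd(x)
}

#' Colored 1/f^alpha noise
#'
#' Spectral-synthesis colored noise: Gaussian white spectrum shaped by
#' `f^(-alpha/2)`, inverse-transformed and z-scored (mean 0, SD 1 exactly).
#'
#' @param duration length (s).
#' @param dt sample step (ms).
#' @param exponent spectral exponent alpha > 0 (default 1.5).
#' @param seed optional integer seed.
#' @return numeric vector, z-scored.
#' @export
colored_noise <- function(duration, dt = 0.05, exponent = 1.5, seed = NULL) {
  if (exponent <= 0)
    stop("invalid configuration: exponent must be positive", call. = FALSE)
  n <- round(duration * 1000 / dt)
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
  }
  nf <- n %/% 2
  f <- seq_len(nf)  # cycles per record; shape is scale-free
  amp <- f^(-exponent / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(fft(full, inverse = TRUE))
  as.numeric(scale(x))
}

#' Reversal-locked envelope
#'
#' Normalized transient locked to a grating contrast reversal: linear rise
#' from 0 to 1 over the first 10 ms, then exponential decay at 25 1/s (time
#' constant 40 ms), so the transient is over within ~200 ms.  Zero for
#' negative times.
#'
#' @param t_rel time since the reversal (ms); vectorized.
#' @return envelope values in `[0, 1]`.
#' @export
#' @examples
#' reversal_envelope(c(0, 10, 50))  # 0, 1, exp(-1)
reversal_envelope <- function(t_rel) {
  out <- numeric(length(t_rel))
  rise <- t_rel >= 0 & t_rel < 10
  decay <- t_rel >= 10
  out[rise] <- t_rel[rise] / 10
  out[decay] <- exp(-25 * (t_rel[decay] - 10) / 1000)
  out
}

#' Thalamic rate signal
#'
#' Evaluates `nu(t) = [S(K,t) + A(K,t) eps_gamma(t) + theta_n n(t)]_+` on the
#' simulation grid.  With `reversal_times` empty (or `alpha = beta = 0`) the
#' rate is statistically stationary; otherwise the periodic amplitude dips by
#' `alpha * f(t - t* - Dt)` (delayed by `Dt` = 40 ms) and the sustained rate
#' rises by `beta * f(t - t*)` after every reversal `t*`.
#'
#' @param params a [thalamic_input_params].
#' @param duration length (s).
#' @param dt sample step (ms).
#' @param seed optional integer seed for the two noise realizations.
#' @return object of class `thalamic_rate`: list with `rate` (sp/s, length
#'   `duration*1000/dt`), `eps_gamma`, `S_t`, `A_t`, `dt`, `params`.
#' @export
thalamic_rate <- function(params, duration, dt = 0.05, seed = NULL) {
  stopifnot(inherits(params, "thalamic_input_params"))
  n <- round(duration * 1000 / dt)
  t_ms <- (seq_len(n) - 1) * dt
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
  }
  eps <- gamma_filtered_noise(duration, dt, params$osc_center,
                              params$osc_bandwidth)
  cn <- colored_noise(duration, dt, params$noise_exponent)

  A_t <- rep(params$A0, n)
  S_t <- rep(params$S0, n)
  for (tstar in params$reversal_times * 1000) {
    A_t <- A_t - params$alpha * reversal_envelope(t_ms - tstar - params$latency_Dt)
    S_t <- S_t + params$beta * reversal_envelope(t_ms - tstar)
  }
  A_t <- pmax(A_t, 0)
  rate <- pmax(S_t + A_t * eps + params$noise_amplitude * 1000 * cn, 0)
  structure(list(rate = rate, eps_gamma = eps, S_t = S_t, A_t = A_t,
                 dt = dt, params = params),
            class = "thalamic_rate")
}

#' Draw inhomogeneous Poisson input spike trains
#'
#' Each of `n_neurons` receives an independent realization of a Poisson
#' process with the common time-varying rate, discretized per time step as
#' Bernoulli(`rate*dt`) (with `rate*dt << 1` in all regimes used here).
#'
#' @param rate rate signal (sp/s), one value per step (or a single constant).
#' @param n_neurons number of independent trains.
#' @param duration length (s); required if `rate` is a constant.
#' @param dt step (ms).
#' @param seed optional integer seed.
#' @return object of class `spike_raster`: list with `neuron` (1-based ids),
#'   `time_ms`, `n_neurons`, `duration`, `dt`.
#' @export
draw_input_spikes <- function(rate, n_neurons, duration = NULL, dt = 0.05,
                              seed = NULL) {
  if (inherits(rate, "thalamic_rate")) { dt <- rate$dt; rate <- rate$rate }
  if (length(rate) == 1) {
    if (is.null(duration)) stop("duration required for a constant rate", call. = FALSE)
    rate <- rep(rate, round(duration * 1000 / dt))
  }
  if (any(rate < 0)) stop("rate must be non-negative everywhere", call. = FALSE)
  n <- length(rate)
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
  }
  p <- pmin(rate * dt * 1e-3, 1)
  # per step, the spiking neurons form a uniform random subset of size
  # Binomial(n_neurons, p) -- equivalent to independent Bernoulli thinning
  counts <- rbinom(n, n_neurons, p)
  steps <- rep.int(seq_len(n), counts)
  total <- sum(counts)
  neuron <- integer(total)
  pos <- 1L
  for (i in which(counts > 0L)) {
    m <- counts[i]
    neuron[pos:(pos + m - 1L)] <- sample.int(n_neurons, m)
    pos <- pos + m
  }
  structure(list(neuron = neuron, time_ms = steps * dt,
                 n_neurons = as.integer(n_neurons),
                 duration = n * dt / 1000, dt = dt),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d spikes over %d neurons, %.3g s\n",
              length(x$time_ms), x$n_neurons, x$duration))
  invisible(x)
}
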