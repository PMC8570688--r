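#' Synaptic gate increment kernel
#'
#' Contribution of a single presynaptic spike to the postsynaptic gate
#' variable: a delayed difference of exponentials,
#' `tau_m/(tau_d - tau_r) * (exp(-(t - tau_l)/tau_d) - exp(-(t - tau_l)/tau_r))`
#' for `t >= tau_l`, and 0 before the latency.
#'
#' @param t_rel time since the presynaptic spike (ms); may be a vector.
#' @param syn a [synapse_params] object.
#' @param tau_m membrane time constant of the postsynaptic neuron (ms).
#' @return gate values (dimensionless), same length as `t_rel`.
#' @export
#' @examples
#' syn <- default_synapses()$AMPA_recurrent_excitatory
#' synaptic_gate_increment(c(2, 3, 10), syn, tau_m = 20)
synaptic_gate_increment <- function(t_rel, syn, tau_m) {
  stopifnot(inherits(syn, "synapse_params"))
  if (syn$tau_d == syn$tau_r)
    stop("degenerate kernel: tau_d == tau_r (alpha-function limit not supported)",
         call. = FALSE)
  u <- t_rel - syn$tau_l
  out <- numeric(length(t_rel))
  on <- u >= 0
  out[on] <- tau_m / (syn$tau_d - syn$tau_r) *
    (exp(-u[on] / syn$tau_d) - exp(-u[on] / syn$tau_r))
  out
}

.syn_matrix <- function(synapses) {
  # rows: GABA->E, GABA->I, AMPAr->E, AMPAr->I, AMPAe->E, AMPAe->I
  ord <- c("GABA_excitatory", "GABA_inhibitory",
           "AMPA_recurrent_excitatory", "AMPA_recurrent_inhibitory",
           "AMPA_external_excitatory", "AMPA_external_inhibitory")
  if (!all(ord %in% names(synapses)))
    stop("synapses must contain the six class/target combinations named as in default_synapses()",
         call. = FALSE)
  m <- t(vapply(synapses[ord], function(s) c(s$g_syn, s$tau_l, s$tau_r, s$tau_d),
                numeric(4)))
  vrev <- c(synapses$GABA_excitatory$v_reversal,
            synapses$AMPA_recurrent_excitatory$v_reversal,
            synapses$AMPA_external_excitatory$v_reversal)
  list(m = m, v_rev = vrev)
}

#' Simulate the recurrent E/I network
#'
#' Integrates the conductance-based LIF network with second-order
#' Runge-Kutta at step `config$dt`, drives every neuron with an independent
#' Poisson realization of the external rate, and returns the spike raster,
#' the per-class summed synaptic currents onto excitatory neurons, and the
#' LFP proxy, all after discarding the initial `config$discard_initial` ms.
#'
#' @param populations list with `excitatory` and `inhibitory`
#'   [neuron_population] objects (see [default_populations]).
#' @param synapses named list of six [synapse_params] (see
#'   [default_synapses]).
#' @param connectivity a [build_connectivity] result whose population sizes
#'   match `populations`.
#' @param input external drive: either a list `list(rate = <numeric>)` giving
#'   the thalamic rate (sp/s) on the simulation time grid (one value per dt
#'   step, recycled if a single value), e.g. from [thalamic_rate]; or a spike
#'   raster from [draw_input_spikes]; or a list
#'   `list(neuron = <int>, time_ms = <numeric>)` of explicit external spikes.
#' @param config a [simulation_config].
#' @param v_init optional initial membrane potentials (mV, length N).  By
#'   default potentials are drawn uniformly in `[v_rest, v_threshold)`.
#' @return object of class `sim_output`: `spikes` (data.frame neuron/time_ms,
#'   after discard), `currents` (matrix, columns gaba/ampa_rec/ampa_ext, pA,
#'   per time step after discard), `lfp` (an `lfp_trace`, see [lfp_proxy]),
#'   `time_ms`, `rates` (per-population mean firing rates, sp/s), `config`.
#' @export
simulate_network <- function(populations, synapses, connectivity, input,
                             config = simulation_config(), v_init = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n_exc <- populations$excitatory$count
  n_inh <- populations$inhibitory$count
  if (connectivity$n_exc != n_exc || connectivity$n_inh != n_inh)
    stop("connectivity population sizes do not match the populations",
         call. = FALSE)
  n_steps <- as.integer(round(config$duration * 1000 / config$dt))
  discard_steps <- as.integer(round(config$discard_initial / config$dt))

  ext_rate <- numeric(0)
  ext_neuron <- integer(0)
  ext_time <- numeric(0)
  if (!is.null(input$rate)) {
    ext_rate <- input$rate
    if (length(ext_rate) == 1) ext_rate <- rep(ext_rate, n_steps)
    if (length(ext_rate) < n_steps)
      stop("input rate does not cover the configured duration", call. = FALSE)
    ext_rate <- ext_rate[seq_len(n_steps)]
    if (any(ext_rate < 0)) stop("external rate must be non-negative", call. = FALSE)
  } else if (inherits(input, "spike_raster") ||
             (!is.null(input$neuron) && !is.null(input$time_ms))) {
    ext_neuron <- as.integer(input$neuron) - 1L
    ext_time <- as.numeric(input$time_ms)
    if (length(ext_time) && max(ext_time) > config$duration * 1000 + 1e-9)
      warning("external spikes extend beyond the configured duration; ignored")
    o <- order(ext_time)
    ext_neuron <- ext_neuron[o]
    ext_time <- ext_time[o]
    if (length(ext_neuron) && (min(ext_neuron) < 0 || max(ext_neuron) >= n_exc + n_inh))
      stop("external spike neuron indices out of range", call. = FALSE)
  } else stop("input must provide either $rate or explicit spikes", call. = FALSE)

  sm <- .syn_matrix(synapses)
  pe <- populations$excitatory; pi <- populations$inhibitory

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$rng_seed)
  raw <- .sim_lif_network(
    n_exc, n_inh, connectivity$targets, connectivity$offsets,
    sm$m, sm$v_rev,
    c(pe$tau_m, pi$tau_m), c(pe$g_leak, pi$g_leak),
    c(pe$v_rest, pi$v_rest), c(pe$v_threshold, pi$v_threshold),
    c(pe$v_reset, pi$v_reset), c(pe$refractory, pi$refractory),
    config$dt, n_steps, discard_steps,
    ext_rate, ext_neuron, ext_time,
    if (is.null(v_init)) numeric(0) else as.numeric(v_init))

  keep <- raw$spike_t > config$discard_initial
  spikes <- data.frame(neuron = raw$spike_id[keep], time_ms = raw$spike_t[keep])
  currents <- cbind(gaba = raw$i_gaba, ampa_rec = raw$i_ampa_rec,
                    ampa_ext = raw$i_ampa_ext)
  time_ms <- raw$t_start_ms + (seq_len(nrow(currents)) - 1L) * config$dt
  kept_s <- (config$duration * 1000 - config$discard_initial) / 1000
  rates <- c(
    excitatory = sum(spikes$neuron <= n_exc) / n_exc / kept_s,
    inhibitory = sum(spikes$neuron > n_exc) / n_inh / kept_s)

  structure(list(spikes = spikes, currents = currents,
                 lfp = lfp_proxy(currents, fs = 1000 / config$dt),
                 time_ms = time_ms, rates = rates, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: %d spikes, rates %.2f (exc) / %.2f (inh) sp/s, %d LFP samples @ %g kHz\n",
              nrow(x$spikes), x$rates[1], x$rates[2], length(x$lfp$values),
              x$lfp$fs / 1000))
  invisible(x)
}

#' LFP proxy from synaptic currents
#'
#' The model LFP is the sum of the absolute values of the GABA, recurrent
#' AMPA and external AMPA currents entering the excitatory population,
#' `LFP(t) = |I_GABA(t)| + |I_AMPA_rec(t)| + |I_AMPA_ext(t)|` (pA).
#'
#' @param currents matrix (or data.frame) with one column per synaptic class,
#'   all on the same time grid.
#' @param fs sampling rate of the current traces (Hz).
#' @return an `lfp_trace`: list with `values` (non-negative), `fs`, and
#'   optional metadata fields.
#' @export
#' @examples
#' lfp_proxy(cbind(gaba = c(-1, -2), ampa_rec = c(1, 1), ampa_ext = 0), fs = 1000)
lfp_proxy <- function(currents, fs) {
  currents <- as.matrix(currents)
  if (any(!is.finite(currents)))
    stop("non-finite current values", call. = FALSE)
  vals <- rowSums(abs(currents))
  lfp_trace(vals, fs)
}

#' LFP trace container
#'
#' @param values sampled LFP values.
#' @param fs sampling rate (Hz).
#' @param contrast optional contrast label (%).
#' @param trial optional trial id.
#' @return an object of class `lfp_trace`.
#' @export
lfp_trace <- function(values, fs, contrast = NA_real_, trial = NA_integer_) {
  stopifnot(is.numeric(values), fs > 0)
  structure(list(values = as.numeric(values), fs = fs, contrast = contrast,
                 trial = trial),
            class = "lfp_trace")
}

#' Downsample an LFP trace by bin averaging
#'
#' Averages consecutive non-overlapping bins to reach the target rate
#' (typically 1 kHz, the sampling rate of the experimental recordings the
#' analysis settings assume).
#'
#' @param lfp an `lfp_trace`.
#' @param fs_out target sampling rate (Hz); must divide `lfp$fs`.
#' @return an `lfp_trace` at `fs_out`.
#' @export
downsample_lfp <- function(lfp, fs_out = 1000) {
  stopifnot(inherits(lfp, "lfp_trace"))
  ratio <- lfp$fs / fs_out
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("fs_out must divide the trace sampling rate", call. = FALSE)
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(lfp)
  n <- (length(lfp$values) %/% ratio) * ratio
  v <- colMeans(matrix(lfp$values[seq_len(n)], nrow = ratio))
  lfp_trace(v, fs_out, contrast = lfp$contrast, trial = lfp$trial)
}
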