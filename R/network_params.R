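#' Neuron population parameters
#'
#' Membrane constants of one LIF population.  The network equations are
#' `tau_m dV/dt = -(V - v_rest) + I_tot/g_leak`, with a hard threshold,
#' reset, and absolute refractory period.  The synaptic conductances and
#' kinetics are fixed model constants; the membrane constants below are
#' calibrated so that, at the model's baseline thalamic drive (sustained
#' rate 500 sp/s through a single external synapse per neuron), the network
#' fires sparsely, the LFP shows a broad gamma spectrum that strengthens
#' with the sustained drive, and a ~57 Hz periodic input component entrains
#' a narrow-band LFP peak at the input frequency.  See the methods vignette
#' for the calibration rationale; all values can be overridden here.
#'
#' @param population_label "excitatory" or "inhibitory".
#' @param count number of neurons.
#' @param tau_m membrane time constant (ms).
#' @param g_leak leak conductance (nS).
#' @param v_rest resting potential (mV).
#' @param v_threshold spike threshold (mV).
#' @param v_reset post-spike reset potential (mV).
#' @param refractory absolute refractory period (ms).
#' @return an object of class `neuron_population`.
#' @export
#' @examples
#' neuron_population("excitatory", 4000)
neuron_population <- function(population_label = c("excitatory", "inhibitory"),
                              count,
                              tau_m = 20,
                              g_leak = if (population_label == "excitatory") 25 else 20,
                              v_rest = -70, v_threshold = -62, v_reset = -67,
                              refractory = if (population_label == "excitatory") 2 else 1) {
  population_label <- match.arg(population_label)
  if (!is.numeric(count) || length(count) != 1 || count <= 0 ||
      count != round(count))
    stop("invalid configuration: count must be a positive integer", call. = FALSE)
  if (tau_m <= 0 || g_leak <= 0)
    stop("invalid configuration: tau_m and g_leak must be positive", call. = FALSE)
  if (v_reset >= v_threshold)
    stop("invalid configuration: v_reset must lie below v_threshold", call. = FALSE)
  if (refractory < 0)
    stop("invalid configuration: refractory must be non-negative", call. = FALSE)
  structure(list(population_label = population_label, count = as.integer(count),
                 tau_m = tau_m, g_leak = g_leak, v_rest = v_rest,
                 v_threshold = v_threshold, v_reset = v_reset,
                 refractory = refractory),
            class = "neuron_population")
}

#' Synapse parameters
#'
#' One synapse class acting on one target population.  Conductances and
#' kinetics follow the model's synaptic parameter table; reversal potentials
#' are -80 mV (GABA) and 0 mV (AMPA).
#'
#' @param synapse_class one of "GABA", "AMPA_recurrent", "AMPA_external".
#' @param target_population "excitatory" or "inhibitory".
#' @param g_syn synaptic conductance (nS).
#' @param tau_l latency (ms).
#' @param tau_r rise time constant (ms).
#' @param tau_d decay time constant (ms).
#' @param v_reversal reversal potential (mV).
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(synapse_class = c("GABA", "AMPA_recurrent", "AMPA_external"),
                           target_population = c("excitatory", "inhibitory"),
                           g_syn, tau_l, tau_r, tau_d,
                           v_reversal = if (synapse_class == "GABA") -80 else 0) {
  synapse_class <- match.arg(synapse_class)
  target_population <- match.arg(target_population)
  if (g_syn <= 0) stop("invalid configuration: g_syn must be positive", call. = FALSE)
  if (tau_l < 0) stop("invalid configuration: tau_l must be non-negative", call. = FALSE)
  if (!(tau_d > tau_r && tau_r > 0))
    stop("invalid configuration: require tau_d > tau_r > 0", call. = FALSE)
  structure(list(synapse_class = synapse_class,
                 target_population = target_population,
                 g_syn = g_syn, tau_l = tau_l, tau_r = tau_r, tau_d = tau_d,
                 v_reversal = v_reversal),
            class = "synapse_params")
}

#' Default synaptic parameter set
#'
#' The six (class x target) synapse definitions of the model: GABA, recurrent
#' AMPA and external AMPA, each onto excitatory and inhibitory neurons.
#'
#' @return a named list of six [synapse_params] objects.
#' @export
#' @examples
#' default_synapses()$AMPA_recurrent_excitatory$tau_d  # 2.25 ms
default_synapses <- function() {
  list(
    GABA_inhibitory = synapse_params("GABA", "inhibitory", 2.700, 1, 1, 5),
    GABA_excitatory = synapse_params("GABA", "excitatory", 2.010, 1, 1, 5),
    AMPA_recurrent_inhibitory = synapse_params("AMPA_recurrent", "inhibitory",
                                               0.233, 2, 0.2, 1.25),
    AMPA_recurrent_excitatory = synapse_params("AMPA_recurrent", "excitatory",
                                               0.178, 2, 0.4, 2.25),
    AMPA_external_inhibitory = synapse_params("AMPA_external", "inhibitory",
                                              0.317, 2, 0.2, 1.25),
    AMPA_external_excitatory = synapse_params("AMPA_external", "excitatory",
                                              0.234, 2, 0.4, 2.25))
}

#' Default neuron populations
#'
#' @param n_exc,n_inh population sizes (defaults 4000/1000, the 80/20 split
#'   of the 5000-neuron network).
#' @param ... overrides passed to both [neuron_population] calls.
#' @return list with elements `excitatory` and `inhibitory`.
#' @export
default_populations <- function(n_exc = 4000, n_inh = 1000, ...) {
  list(excitatory = neuron_population("excitatory", n_exc, ...),
       inhibitory = neuron_population("inhibitory", n_inh, ...))
}

#' Simulation configuration
#'
#' @param dt integration step (ms); default 0.05 ms.
#' @param duration simulated time (s), including the discarded transient.
#' @param discard_initial initial transient to discard (ms); default 200 ms.
#' @param n_repetitions number of repetitions with fresh noise realizations.
#' @param rng_seed integer seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.05, duration = 2, discard_initial = 200,
                              n_repetitions = 1, rng_seed = 1L) {
  if (dt <= 0) stop("invalid configuration: dt must be positive", call. = FALSE)
  if (discard_initial < 0)
    stop("invalid configuration: discard_initial must be non-negative", call. = FALSE)
  if (duration * 1000 <= discard_initial)
    stop("invalid configuration: duration must exceed the discarded transient",
         call. = FALSE)
  structure(list(dt = dt, duration = duration,
                 discard_initial = discard_initial,
                 n_repetitions = as.integer(n_repetitions),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}
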