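# Small-network factory for unit tests: same 80/20 structure and synapse
# table as the full model, scaled down for speed.
small_network <- function(n_exc = 80, n_inh = 20, p = 0.2, seed = 1,
                          ...) {
  list(populations = list(
         excitatory = neuron_population("excitatory", n_exc, ...),
         inhibitory = neuron_population("inhibitory", n_inh, ...)),
       synapses = default_synapses(),
       connectivity = build_connectivity(n_exc, n_inh, p, seed))
}

# A single isolated neuron with negligible synaptic conductances: its
# recorded currents are then proportional to the synaptic gate variable,
# which lets tests read the gate time course directly.
gate_probe_network <- function(g_scale = 1e-8) {
  syn <- default_synapses()
  for (nm in names(syn)) syn[[nm]]$g_syn <- syn[[nm]]$g_syn * g_scale
  list(populations = list(
         excitatory = neuron_population("excitatory", 1),
         inhibitory = neuron_population("inhibitory", 1)),
       synapses = syn,
       connectivity = build_connectivity(1, 1, 0, seed = 1))
}
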