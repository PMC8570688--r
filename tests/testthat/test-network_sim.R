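test_that("connectivity has binomial in-degrees and honors the seed", {
  cm <- build_connectivity(400, 100, 0.2, seed = 3)
  n <- 500
  out_deg <- diff(cm$offsets)
  # out-degree of each neuron ~ Binomial(N-1, p)
  expect_equal(length(out_deg), n)
  mu <- 0.2 * (n - 1)
  sdev <- sqrt(n * 0.2 * 0.8 * (n - 1)) / n  # SE of the mean out-degree
  expect_lt(abs(mean(out_deg) - mu), 3 * sqrt(0.2 * 0.8 * (n - 1) / n) + 1)
  # no self-connections
  for (j in sample(n, 20)) {
    tg <- cm$targets[(cm$offsets[j] + 1):cm$offsets[j + 1]]
    expect_false((j - 1) %in% tg)
  }
  cm2 <- build_connectivity(400, 100, 0.2, seed = 3)
  expect_identical(cm$targets, cm2$targets)
  cm3 <- build_connectivity(400, 100, 0.2, seed = 4)
  expect_false(identical(cm$targets, cm3$targets))
})

test_that("degenerate connectivity configurations are rejected or empty", {
  expect_equal(length(build_connectivity(50, 10, 0)$targets), 0)
  expect_error(build_connectivity(50, 10, 1.2), "invalid configuration")
  expect_error(build_connectivity(-5, 10, 0.2), "invalid configuration")
})

test_that("synaptic gate kernel matches its closed form and brute-force peak", {
  syn <- default_synapses()$AMPA_recurrent_excitatory  # tau_r 0.4, tau_d 2.25
  tau_m <- 20
  expect_equal(synaptic_gate_increment(syn$tau_l, syn, tau_m), 0)
  expect_lt(synaptic_gate_increment(200, syn, tau_m), 1e-10)
  expect_equal(synaptic_gate_increment(1, syn, tau_m), 0)  # before latency
  # dense evaluation on a 1 us grid: peak location and value
  tt <- seq(syn$tau_l, syn$tau_l + 20, by = 1e-3)
  kern <- tau_m / (syn$tau_d - syn$tau_r) *
    (exp(-(tt - syn$tau_l) / syn$tau_d) - exp(-(tt - syn$tau_l) / syn$tau_r))
  expect_equal(synaptic_gate_increment(tt, syn, tau_m), kern, tolerance = 1e-12)
  t_peak_analytic <- syn$tau_l + log(syn$tau_d / syn$tau_r) *
    syn$tau_r * syn$tau_d / (syn$tau_d - syn$tau_r)
  expect_equal(tt[which.max(kern)], t_peak_analytic, tolerance = 1e-2)
  bad <- syn; bad$tau_d <- bad$tau_r
  expect_error(synaptic_gate_increment(1, bad, tau_m), "degenerate")
})

test_that("a quiescent network stays silent with zero LFP", {
  net <- small_network()
  n <- 100
  cfg <- simulation_config(duration = 0.4, discard_initial = 100, rng_seed = 5)
  v_rest <- rep(-70, n)
  out <- simulate_network(net$populations, net$synapses, net$connectivity,
                          list(neuron = integer(0), time_ms = numeric(0)),
                          cfg, v_init = v_rest)
  expect_equal(nrow(out$spikes), 0)
  expect_true(all(out$lfp$values == 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  net <- small_network()
  cfg <- simulation_config(duration = 0.6, discard_initial = 100, rng_seed = 11)
  inp <- list(rate = 3000)
  a <- simulate_network(net$populations, net$synapses, net$connectivity, inp, cfg)
  b <- simulate_network(net$populations, net$synapses, net$connectivity, inp, cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$currents, b$currents)
  cfg2 <- simulation_config(duration = 0.6, discard_initial = 100, rng_seed = 12)
  c <- simulate_network(net$populations, net$synapses, net$connectivity, inp, cfg2)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("no neuron violates its refractory period", {
  net <- small_network(n_exc = 40, n_inh = 10)
  cfg <- simulation_config(duration = 1, discard_initial = 0, rng_seed = 2)
  out <- simulate_network(net$populations, net$synapses, net$connectivity,
                          list(rate = 6000), cfg)
  expect_gt(nrow(out$spikes), 100)  # drive strong enough to matter
  for (pop_refr in list(c(1, 40, 2), c(41, 50, 1))) {
    sel <- out$spikes$neuron >= pop_refr[1] & out$spikes$neuron <= pop_refr[2]
    sp <- out$spikes[sel, ]
    isi <- unlist(lapply(split(sp$time_ms, sp$neuron), function(t) diff(sort(t))))
    if (length(isi)) expect_gte(min(isi), pop_refr[3] - 1e-9)
  }
})

test_that("gate accumulation is a superposition of shifted kernels", {
  net <- gate_probe_network()
  cfg <- simulation_config(duration = 0.1, discard_initial = 0, rng_seed = 1)
  spikes <- list(neuron = c(1L, 1L), time_ms = c(10, 13.7))
  out <- simulate_network(net$populations, net$synapses, net$connectivity,
                          spikes, cfg, v_init = c(-70, -70))
  syn <- net$synapses$AMPA_external_excitatory
  # with vanishing conductances V stays at rest, so
  # |I_ext|(t) = g * s(t) * |v_rest - 0| and s(t) = sum of shifted kernels
  s_meas <- out$currents[, "ampa_ext"] / (syn$g_syn * 70)
  expected <- synaptic_gate_increment(out$time_ms - 10, syn, 20) +
    synaptic_gate_increment(out$time_ms - 13.7, syn, 20)
  expect_lt(max(abs(s_meas - expected)), 1e-9)
})

test_that("RK2 at dt = 0.05 ms matches a 10x finer integration", {
  net <- small_network(n_exc = 80, n_inh = 20, seed = 7)
  set.seed(99)
  raster <- draw_input_spikes(4000, n_neurons = 100, duration = 1, dt = 0.05)
  v0 <- rep(-65, 100)
  counts <- sapply(c(0.05, 0.005), function(dt) {
    cfg <- simulation_config(dt = dt, duration = 1, discard_initial = 0,
                             rng_seed = 1)
    out <- simulate_network(net$populations, net$synapses, net$connectivity,
                            raster, cfg, v_init = v0)
    nrow(out$spikes)
  })
  expect_gt(counts[1], 200)
  expect_lt(abs(counts[1] - counts[2]) / counts[2], 0.01)
})

test_that("mean LFP amplitude grows with the sustained drive", {
  net <- small_network(n_exc = 160, n_inh = 40, seed = 3)
  S_grid <- seq(500, 1000, by = 100)
  means <- sapply(seq_along(S_grid), function(i) {
    mean(sapply(1:5, function(r) {
      run <- simulate_lfp(net, thalamic_input_params(
        K = NA, A0 = 0, alpha = 0, S0 = S_grid[i], beta = 0),
        duration = 0.7, seed = 100 * i + r, discard = 200)
      mean(run$lfp$values)
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("the LFP proxy is the sum of absolute class currents", {
  cur <- cbind(gaba = c(-3, 2, 0), ampa_rec = c(1, -1, 0), ampa_ext = c(0.5, 0, 0))
  lfp <- lfp_proxy(cur, fs = 1000)
  expect_equal(lfp$values, c(4.5, 3, 0))
  expect_equal(lfp_proxy(2 * cur, fs = 1000)$values, 2 * lfp$values)
  flipped <- cur; flipped[, "gaba"] <- -flipped[, "gaba"]
  expect_equal(lfp_proxy(flipped, fs = 1000)$values, lfp$values)
})

test_that("downsampling preserves means and rejects non-integer ratios", {
  x <- lfp_trace(rep(c(1, 3), 500), fs = 20000)
  d <- downsample_lfp(x, 1000)
  expect_equal(d$values, rep(2, 50))
  expect_error(downsample_lfp(x, 999), "divide")
})
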