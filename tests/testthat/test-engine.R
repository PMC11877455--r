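test_that("membrane Euler step matches the closed-form exponential within 0.1%", {
  np <- neuron_params()                      # tau_m = Cm/gL = 20 ms
  dt <- 0.05
  vm <- -55
  clock <- 0
  for (i in seq_len(400)) {                  # one membrane time constant
    st <- step_membrane(vm, clock, np, Isyn = 0, Istim = 0, dt = dt)
    vm <- st$vm; clock <- st$ref_clock
  }
  expect_equal(vm, -70 + 15 * exp(-1), tolerance = 1e-3)
  expect_equal(vm, -64.48, tolerance = 1e-3)
})

test_that("threshold crossing resets, starts refractoriness, suppresses re-fire", {
  np <- neuron_params()
  st <- step_membrane(-50.001, 0, np, Isyn = 0, Istim = 1e6, dt = 0.05)
  expect_true(st$spiked)
  expect_equal(st$vm, np$Vr)
  expect_equal(st$ref_clock, np$tau_r)
  # while refractory the membrane stays clamped and cannot spike
  st2 <- step_membrane(st$vm, st$ref_clock, np, 0, 1e6, dt = 0.05)
  expect_false(st2$spiked)
  expect_equal(st2$vm, np$Vr)
})

test_that("gating variables decay like the Euler exponential and stay bounded", {
  syn <- synapse_params()
  g <- list(s_ampa_ext = 1, s_ampa_rec = 1, x_nmda = 0, s_nmda = 1, s_gaba = 1)
  for (i in 1:40) g <- step_gating(g, syn, dt = 0.05)   # 2 ms = tau_AMPA
  expect_equal(g$s_ampa_ext, (1 - 0.05 / 2)^40, tolerance = 1e-10)
  expect_equal(g$s_ampa_ext, 0.364, tolerance = 3e-3)   # ~= exp(-1)
  expect_lt(abs(g$s_ampa_ext - exp(-1)), 0.005)
  expect_true(g$s_nmda < 1 && g$s_nmda > 0)             # decays, never > 1

  # property: s_NMDA in [0,1], all gating >= 0 under random spike bombardment
  set.seed(42)
  g <- list(s_ampa_ext = 0, s_ampa_rec = 0, x_nmda = 0, s_nmda = 0, s_gaba = 0)
  for (i in 1:2000) {
    arr <- if (runif(1) < 0.3) list(ext = 1L, rec_exc = 1L, rec_inh = 1L)
           else list(ext = integer(0), rec_exc = integer(0),
                     rec_inh = integer(0))
    g <- step_gating(g, syn, dt = 0.05, arrivals = arr)
    expect_true(g$s_nmda >= 0 && g$s_nmda <= 1)
    expect_true(all(unlist(g) >= 0))
  }
  # one arrival increments by exactly one unit
  g0 <- list(s_ampa_ext = 0, s_ampa_rec = 0, x_nmda = 0, s_nmda = 0, s_gaba = 0)
  g1 <- step_gating(g0, syn, 0.05, list(ext = 1L, rec_exc = 1L, rec_inh = 1L))
  expect_equal(g1$s_ampa_ext, 1)
  expect_equal(g1$x_nmda, 1)
  expect_equal(g1$s_gaba, 1)
})

test_that("synaptic current equations match hand-evaluated examples", {
  syn <- synapse_params()
  # NMDA magnesium divisor at -70 mV
  expect_equal(1 + syn$C_Mg * exp(-62 * -0.070) / 3.57, 22.49, tolerance = 1e-3)

  net <- build_network(network_architecture(variant = "recurrent_only",
                                            w_rec = 1), seed = 1)
  n <- nrow(net$neurons)
  zero <- list(s_ampa_ext = rep(0, n), s_ampa_rec = rep(0, n),
               x_nmda = rep(0, n), s_nmda = rep(0, n), s_gaba = rep(0, n))
  cur0 <- synaptic_currents(zero, syn, rep(-70, n), net)
  expect_true(all(as.matrix(cur0) == 0))

  # single active synapse: I = g * s * (E - Vm), weight 1
  syn1 <- synapse_params(g_ampa_rec = c(1, 1))
  g1 <- zero; g1$s_ampa_rec[2] <- 1
  cur1 <- synaptic_currents(g1, syn1, rep(-70, n), net)
  expect_equal(cur1$I_ampa_rec[1], 1 * 1 * (0 - -70))   # 70 pA onto others
  expect_equal(cur1$I_ampa_rec[2], 0)                   # no self-connection
})

test_that("trials are deterministic per seed and respect absolute refractoriness", {
  cfg <- tiny_disconnected_config()
  net <- build_network(cfg$network, seed = 5)
  a <- run_trial(cfg, seed = 99, network = net)
  b <- run_trial(cfg, seed = 99, network = net)
  expect_identical(a$spikes, b$spikes)
  c <- run_trial(cfg, seed = 100, network = net)
  expect_false(identical(a$spikes, c$spikes))

  isi <- dplyr::summarise(dplyr::group_by(a$spikes, neuron_id),
                          min_isi = min(diff(t_ms), Inf))
  expect_true(all(isi$min_isi >= cfg$neurons_pyr$tau_r))
  # spike times strictly increasing per neuron (recording invariant)
  expect_true(all(unlist(tapply(a$spikes$t_ms, a$spikes$neuron_id,
                                function(x) diff(x) > 0))))
})

test_that("no neuron spikes from rest without synaptic or stimulation input", {
  cfg <- tiny_disconnected_config(
    synapses = synapse_params(g_ampa_ext = c(0, 0), g_ampa_rec = c(0, 0),
                              g_nmda = c(0, 0), g_gaba = c(0, 0)))
  rec <- run_trial(cfg, seed = 1)
  expect_equal(nrow(rec$spikes), 0)
})

test_that("galvanic drive reproduces the closed-form suprathreshold firing rate", {
  # isolated neurons, no synaptic input, constant Istim inside the window:
  # the analytic LIF rate is the independent oracle
  el <- electrode_model(k_gs = 150)
  cfg <- sim_config(
    network = network_architecture(variant = "disconnected"),
    electrode = el,
    synapses = synapse_params(g_ampa_ext = c(0, 0)),
    background_rate_hz = 0,
    task = task_config(0, base_rate_hz = 0, gain_hz = 0),
    stimulation = stim_protocol("CGS", amplitude_uA = -1.4))
  net <- build_network(cfg$network, seed = 2)
  net$neurons$distance_um <- rep(50, 120)
  rec <- run_trial(cfg, seed = 1, network = net)

  istim <- el$k_gs * mirror_vmss(50, el, I_uA = -1.4)
  np <- neuron_params()
  v_inf <- np$EL + istim / np$gL
  tau_m <- np$Cm / np$gL * 1e3
  isi <- np$tau_r + tau_m * log((v_inf - np$Vr) / (v_inf - np$Vthreshold))
  expected <- 2000 / isi                      # spikes in the 2 s window
  sp <- rec$spikes[rec$spikes$t_ms > 1000 & rec$spikes$t_ms <= 3000, ]
  per_neuron <- tabulate(sp$neuron_id, nbins = 120)
  expect_equal(mean(per_neuron), expected, tolerance = 0.03)
  expect_equal(stats::var(per_neuron), 0)     # fully deterministic drive
  expect_equal(nrow(rec$spikes[rec$spikes$t_ms <= 1000, ]), 0)
})

test_that("full network shows spontaneous rates in the physiological bands", {
  cfg <- sim_config(task = task_config(0, base_rate_hz = 0, gain_hz = 0),
                    duration_s = 2)
  rec <- run_trial(cfg, seed = 31)
  rate <- function(p) sum(rec$spikes$population == p) / 2 /
    sum(rec$neurons$population == p)
  expect_lt(rate("P1"), 5); expect_lt(rate("P2"), 5); expect_lt(rate("NS"), 5)
  expect_gt(rate("Int"), rate("P1"))
  expect_gt(rate("Int"), 3); expect_lt(rate("Int"), 12)
})

test_that("the winning attractor self-perpetuates after task offset", {
  cfg <- sim_config(task = task_config(coherence = 1))
  rec <- run_trial(cfg, seed = 17)
  d <- decide(rec)
  expect_equal(d$winner, "P1")
  rts <- smoothed_rates(rec, populations = c("P1", "P2"))
  pr <- rts$population
  post <- function(p) mean(pr$rate[pr$population == p & pr$t_s > 3.4])
  expect_gt(post("P1"), 15)    # sustained without task input
  expect_lt(post("P2"), 10)
})
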