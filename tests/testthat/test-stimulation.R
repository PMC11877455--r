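test_that("point-source potential follows rho*I/(4*pi*r)", {
  expect_equal(extracellular_potential(100, 10, 3.0), 23.87324, tolerance = 1e-6)
  expect_equal(extracellular_potential(500, 0, 3.0), 0)
  r <- c(50, 100, 200, 400)
  v <- extracellular_potential(r, -1.4, 3.0)
  expect_equal(v[-1] / v[-4], c(1 / 2, 1 / 2, 1 / 2))   # 1/r scaling
  expect_true(all(v < 0))                               # sign follows current
  expect_error(extracellular_potential(0, 1), "positive")
})

test_that("mirror estimate matches hand-evaluated 3-node example", {
  el <- electrode_model(axon_nodes = 3, axon_spacing_um = 100)
  vext <- extracellular_potential(axon_node_distances(100, el), -1.4, el$rho_ext)
  expect_equal(vext, c(-3.342254, -2.363334, -1.494684), tolerance = 1e-4)
  expect_equal(mirror_vmss(100, el, I_uA = -1.4), 0.9421586, tolerance = 1e-4)
})

test_that("mirror polarization conserves to zero and decays with distance", {
  el <- electrode_model()
  for (r in c(10, 137, 1500)) {
    expect_equal(sum(mirror_vmss(r, el, I_uA = -2, all_nodes = TRUE)), 0,
                 tolerance = 1e-12)
  }
  vm <- vapply(c(10, 30, 100, 300, 1000, 2000), mirror_vmss, numeric(1),
               electrode = el, I_uA = -1.4)
  expect_true(all(vm > 0))            # cathodic depolarizes the closest node
  expect_true(all(diff(vm) < 0))      # monotone decay with distance
})

test_that("stimulation current is proportional and pulse-gated", {
  el <- electrode_model(k_gs = 100, k_ps = 350)
  expect_equal(stim_current(1, "CGS", el), 100)
  expect_equal(stim_current(2, "PS", el, within_pulse = FALSE), 0)
  expect_equal(stim_current(2, "PS", el, within_pulse = TRUE), 700)
  # AGS at -CGS amplitude flips the sign everywhere
  vm <- mirror_vmss(c(50), el, I_uA = -1.4)
  expect_equal(stim_current(vm, "CGS", el),
               -stim_current(-vm, "AGS", el))
})

test_that("biphasic waveform is cathodic-first, 600 us footprint, charge balanced", {
  p <- stim_protocol("PS", amplitude_uA = -10)
  t <- seq(1000.005, 1004.995, by = 0.01)   # one 5 ms period at 200 pps
  w <- pulse_waveform(p, t)
  expect_equal(w$phase[1], "cathodic")
  expect_equal(sum(w$phase != "off") * 0.01, 0.6, tolerance = 0.02)
  expect_equal(sum(w$I_uA) * 0.01, 0, tolerance = 1e-8)       # charge balance
  expect_true(all(w$I_uA[w$phase == "cathodic"] == -10))
  expect_true(all(w$I_uA[w$phase == "anodic"] == 10))
  # outside the stimulation window everything is off
  expect_true(all(pulse_waveform(p, c(0, 500, 3500))$phase == "off"))
  expect_error(stim_protocol("PS", pulse_rate_pps = 2000), "overlap")
})

test_that("refractory interpolation clamps at anchors and halves when renewed", {
  tab <- cbind(c(0, 240), c(0, 132))
  expect_equal(refractory_time(120, tab), 66)
  expect_equal(refractory_time(120, tab, already_refractory = TRUE), 33)
  expect_equal(refractory_time(-5, tab), 0)       # below lowest anchor
  expect_equal(refractory_time(1e4, tab), 132)    # clamped at highest
  # vectorized over neurons
  expect_equal(refractory_time(c(0, 120, 240, 500), tab), c(0, 66, 132, 132))
  expect_error(refractory_time(1, tab[0, , drop = FALSE]), "empty|anchors")
})

test_that("refractory gate suppresses only the matching AP class", {
  expect_false(refractory_gate(5, 0, "pulse_induced"))
  expect_true(refractory_gate(5, 0, "spontaneous"))
  expect_false(refractory_gate(0, 5, "spontaneous"))
  expect_true(refractory_gate(0, 0, "pulse_induced"))
})

test_that("galvanic block gate zeroes currents above the cap, non-strict boundary", {
  p <- stim_protocol("CGS", amplitude_uA = -1.4)
  expect_equal(galvanic_block_gate(c(1000, 1135, 1200), p), c(1000, 1135, 0))
})

test_that("placement is uniform on 10-2000 um and seed-reproducible", {
  pl <- place_neurons(5000, seed = 7)
  expect_equal(nrow(pl), 5000)
  expect_true(all(pl$distance_um >= 10 & pl$distance_um <= 2000))
  expect_equal(mean(pl$distance_um), 1005, tolerance = 0.03)
  expect_identical(pl, place_neurons(5000, seed = 7))
  expect_false(isTRUE(all.equal(pl$distance_um,
                                place_neurons(5000, seed = 8)$distance_um)))
})
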