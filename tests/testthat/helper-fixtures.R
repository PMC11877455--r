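# shared tiny fixtures built in code

tiny_disconnected_config <- function(duration_s = 2, ...) {
  sim_config(network = network_architecture(variant = "disconnected"),
             duration_s = duration_s, ...)
}

# hand-built trial recording for analysis-side tests: explicit spike times,
# no simulation involved
fake_trial <- function(spike_list, duration_s = 4, n_neurons = length(spike_list),
                       populations = rep("P1", n_neurons),
                       stimulation = stim_protocol("none"),
                       distances = seq(100, by = 100,
                                       length.out = n_neurons)) {
  neurons <- tibble::tibble(
    neuron_id = seq_len(n_neurons),
    population = factor(populations, levels = c("P1", "P2", "NS", "Int")),
    class = "pyr", distance_um = distances)
  spikes <- dplyr::bind_rows(purrr::imap(spike_list, function(ts, i) {
    i <- as.integer(i)
    tibble::tibble(neuron_id = i, population = neurons$population[i],
                   distance_um = neurons$distance_um[i], t_ms = sort(ts))
  }))
  structure(list(
    spikes = spikes, neurons = neurons, condition = stimulation$mode,
    coherence = 0, seed = 0L, dt_ms = 0.05, duration_ms = duration_s * 1e3,
    config = sim_config(stimulation = stimulation)), class = "wta_trial")
}

# regular spike train (ms)
regular_train <- function(rate_hz, t0_ms = 0, t1_ms = 4000) {
  seq(t0_ms + 1000 / rate_hz, t1_ms, by = 1000 / rate_hz)
}
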