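#' Extracellular potential of a point-source electrode
#'
#' Potential at distance `r_um` from a monopolar point source in a homogeneous
#' medium of resistivity `rho_ext`: Vext = rho I / (4 pi r).
#'
#' @param r_um Distance(s) from the electrode (um); must be > 0.
#' @param I_uA Electrode current (uA); cathodic currents are negative.
#' @param rho_ext Extracellular resistivity (Ohm m).
#' @return Extracellular potential (mV), same length as `r_um`.
#' @export
#' @examples
#' extracellular_potential(100, 10, 3)  # ~23.87 mV
extracellular_potential <- function(r_um, I_uA, rho_ext = 3.0) {
  if (any(r_um <= 0)) stop("r_um must be positive", call. = FALSE)
  # rho [Ohm m] * I [A] / (4 pi r [m]) -> V; scaled to mV with uA and um
  rho_ext * (I_uA * 1e-6) / (4 * pi * r_um * 1e-6) * 1e3
}

#' Axon node distances for the mirror estimate
#'
#' The mirror estimate uses a straight axon with `axon_nodes` nodes spaced
#' `axon_spacing_um` apart; the electrode sits at perpendicular distance
#' `r_closest_um` from the first (closest) node, with the remaining nodes
#' extending along the axon.
#'
#' @param r_closest_um Perpendicular electrode-axon distance (um).
#' @param electrode An [electrode_model()].
#' @return Numeric vector of node-electrode distances (um).
#' @export
axon_node_distances <- function(r_closest_um, electrode = electrode_model()) {
  offsets <- (seq_len(electrode$axon_nodes) - 1) * electrode$axon_spacing_um
  sqrt(r_closest_um^2 + offsets^2)
}

#' Mirror-estimate steady-state membrane polarization
#'
#' For each axon node, the steady-state membrane polarization under the mirror
#' estimate is the mean extracellular potential along the axon minus the local
#' potential: Vmss = mean(Vext) - Vext(node). Cathodic current therefore
#' depolarizes (positive Vmss) the node closest to the electrode. The sum of
#' Vmss over nodes is identically zero.
#'
#' @inheritParams axon_node_distances
#' @param I_uA Electrode current (uA).
#' @param all_nodes If `TRUE`, return Vmss at every node; otherwise (default)
#'   only at the closest node.
#' @return Vmss (mV).
#' @export
#' @examples
#' mirror_vmss(100, electrode_model(axon_nodes = 3, axon_spacing_um = 100),
#'             I_uA = -1.4)  # ~ +0.942 mV
mirror_vmss <- function(r_closest_um, electrode = electrode_model(),
                        I_uA = 1, all_nodes = FALSE) {
  r <- axon_node_distances(r_closest_um, electrode)
  if (length(unique(r)) == 1 && length(r) > 1 && electrode$axon_spacing_um <= 0) {
    stop("degenerate axon geometry: all nodes coincide", call. = FALSE)
  }
  vext <- extracellular_potential(r, I_uA, electrode$rho_ext)
  vmss <- mean(vext) - vext
  if (all_nodes) vmss else vmss[1]
}

#' Stimulation current injected into a LIF neuron
#'
#' The injected current is proportional to the mirror-estimate polarization:
#' Istim = k_gs Vmss for galvanic stimulation (delivered for the whole
#' stimulation window) and Istim = k_ps Vmss for pulsatile stimulation
#' (delivered only during pulse phases).
#'
#' @param vmss_mV Steady-state polarization at the neuron's closest node (mV).
#' @param mode `"PS"`, `"CGS"` or `"AGS"`.
#' @param electrode An [electrode_model()].
#' @param within_pulse For PS, whether the instant lies inside a pulse phase.
#' @return Injected current (pA).
#' @export
stim_current <- function(vmss_mV, mode, electrode = electrode_model(),
                         within_pulse = TRUE) {
  stopifnot(mode %in% c("PS", "CGS", "AGS"))
  if (mode == "PS") {
    if (within_pulse) electrode$k_ps * vmss_mV else 0 * vmss_mV
  } else {
    electrode$k_gs * vmss_mV
  }
}

#' Biphasic pulse waveform
#'
#' Charge-balanced rectangular biphasic pulses, cathodic phase first, repeating
#' at `pulse_rate_pps` within the stimulation window. The electrode current is
#' `amplitude_uA` (negative, cathodic) during the first phase and
#' `-amplitude_uA` during the second.
#'
#' @param protocol A [stim_protocol()] with `mode = "PS"`.
#' @param t_ms Time point(s) (ms).
#' @return A tibble with columns `t_ms`, `phase` (`"cathodic"`, `"anodic"`,
#'   `"off"`) and `I_uA`.
#' @export
pulse_waveform <- function(protocol, t_ms) {
  stopifnot(protocol$mode == "PS")
  pw <- protocol$pulse_width_us * 1e-3           # ms per phase
  period <- 1000 / protocol$pulse_rate_pps       # ms
  onset <- protocol$onset_s * 1e3
  offset <- protocol$offset_s * 1e3
  inside <- t_ms >= onset & t_ms < offset
  tp <- (t_ms - onset) %% period
  phase <- dplyr::case_when(
    inside & tp < pw ~ "cathodic",
    inside & tp < 2 * pw ~ "anodic",
    TRUE ~ "off"
  )
  I <- dplyr::case_when(
    phase == "cathodic" ~ protocol$amplitude_uA,
    phase == "anodic" ~ -protocol$amplitude_uA,
    TRUE ~ 0
  )
  tibble::tibble(t_ms = t_ms, phase = phase, I_uA = I)
}

#' Amplitude-dependent pulse-pulse refractory period
#'
#' Piecewise-linear interpolation of the refractory anchor table, clamped at
#' the extreme anchors. A pulse arriving while the neuron is already in a
#' pulse-pulse refractory period incurs the halved residual value t_pp / 2.
#'
#' @param amplitude_mV Effective extracellular voltage magnitude at the
#'   neuron's location (mV).
#' @param table Anchor table, two columns `(amplitude_mV, t_pp_ms)`.
#' @param already_refractory Whether a pulse-pulse refractory period is
#'   ongoing.
#' @return Refractory time (ms).
#' @export
#' @examples
#' refractory_time(120, cbind(c(0, 240), c(0, 132)))         # 66
#' refractory_time(120, cbind(c(0, 240), c(0, 132)), TRUE)   # 33
refractory_time <- function(amplitude_mV, table = default_refractory_table(),
                            already_refractory = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 1) stop("empty refractory table", call. = FALSE)
  t_pp <- stats::approx(table[, 1], table[, 2], xout = amplitude_mV,
                        rule = 2)$y
  half <- rep_len(already_refractory, length(t_pp))
  ifelse(half, t_pp / 2, t_pp)
}

#' Refractory gate for a candidate action potential
#'
#' Suppresses only the matching class of action potential: pulse-induced APs
#' while the pulse-pulse clock runs, spontaneous APs while the
#' pulse-spontaneous clock runs. The membrane potential itself is never
#' altered by the gate.
#'
#' @param t_pp_clock,t_ps_clock Remaining refractory times (ms).
#' @param spike_class `"pulse_induced"` or `"spontaneous"`.
#' @return `TRUE` if the AP is allowed.
#' @export
refractory_gate <- function(t_pp_clock, t_ps_clock, spike_class) {
  stopifnot(spike_class %in% c("pulse_induced", "spontaneous"))
  if (spike_class == "pulse_induced") t_pp_clock <= 0 else t_ps_clock <= 0
}

#' Galvanic depolarizing-block gate
#'
#' During galvanic stimulation, instantaneous input currents above the block
#' cap are set to 0 pA for that time step (inputs at or below the cap pass
#' unchanged; the boundary is non-strict).
#'
#' @param I_input_pA Instantaneous input current(s) (pA).
#' @param protocol A [stim_protocol()].
#' @return Gated current(s) (pA).
#' @export
#' @examples
#' galvanic_block_gate(c(1000, 1135, 1200), stim_protocol("CGS"))
galvanic_block_gate <- function(I_input_pA, protocol) {
  ifelse(I_input_pA > protocol$block_cap_pA, 0, I_input_pA)
}

#' Place neurons around the electrode
#'
#' Radial distances are i.i.d. uniform on 10 um - 2 mm, reproducible per seed.
#'
#' @param n Number of neurons.
#' @param seed Integer seed.
#' @param r_min_um,r_max_um Placement range (um).
#' @return A tibble with columns `neuron_id`, `distance_um`.
#' @export
place_neurons <- function(n, seed = 1L, r_min_um = 10, r_max_um = 2000) {
  stopifnot(n > 0)
  r <- withr::with_seed(seed, stats::runif(n, r_min_um, r_max_um))
  tibble::tibble(neuron_id = seq_len(n), distance_um = r)
}
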