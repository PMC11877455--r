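# wtastim

Intracortical microstimulation of a spiking decision-making network, in
silico. `wtastim` asks how two ways of driving cortex through a
microelectrode — conventional biphasic **pulsatile stimulation (PS)** and
sustained direct current (**galvanic stimulation**, cathodic CGS or anodic
AGS) — bias a perceptual decision, and through which network mechanisms. It
is written for computational neuroscientists and neural-engineering groups
who want a reproducible, scriptable testbed for stimulation protocols on a
standard cortical circuit model.

## The model in brief

The circuit is the canonical winner-take-all attractor network of perceptual
decision making: N = 1000 leaky integrate-and-fire neurons (80% pyramidal,
20% interneurons), with two selective pyramidal populations P1 and P2
receiving random-dot-motion task input at FR = 40·c + 40 Hz for signed
coherence c ∈ [−1, 1], all neurons driven by 2400 Hz Poisson background
through AMPA synapses, and recurrence through AMPA, saturating NMDA and
GABA-A conductances with three-level connection weights
(w₊ = 1.7, 1, w₋ = 0.8765). Membrane dynamics follow

dVm/dt = (−gL(Vm − EL) + Isyn + Istim)/Cm,  spike when Vm > Vthreshold.

A trial is decided by whichever selective population's smoothed rate exceeds
15 spk/s at the end of the 4 s trial.

Stimulation enters through a point-source electrode
(Vext = ρI/(4πr)) and the **mirror estimate** along a straight axon
(Vmss = V̄ext − Vext), with Istim = k·Vmss injected into P1 neurons placed
uniformly 10 µm–2 mm from the electrode. Pulses carry amplitude-dependent
pulse–pulse and pulse–spontaneous refractory gating (complete block nearest
the electrode); galvanic stimulation carries a depolarizing-block rule that
zeroes input currents above 1135 pA. The analysis suite covers psychometric
fits with non-parametric bootstrap, decision times, firing-rate
trajectories, population kurtosis over time, phase locking, CV and pairwise
synchrony, and the network-current index (I_AMPA,rec + I_NMDA − I_GABA).

See `vignettes/decision-network-stimulation.Rmd` for the full model
description, parameter provenance and calibration choices.

## Worked example

Bias a decision against the task: task coherence favors P2, pulsatile
stimulation of P1 flips the outcome.

```r
library(wtastim)

cfg <- sim_config(task = task_config(coherence = -0.128),
                  stimulation = condition_protocol("PS"))
net <- build_network(cfg$network, seed = 8)

control <- run_trial(sim_config(task = task_config(-0.128)), seed = 3, network = net)
stimmed <- run_trial(cfg, seed = 3, network = net)
decide(control)
#> # A tibble: 1 x 3
#>   winner decision_time_s excluded_from_timing
#>   <chr>            <dbl> <lgl>
#> 1 P2                1.78 FALSE
decide(stimmed)
#> # A tibble: 1 x 3
#>   winner decision_time_s excluded_from_timing
#>   <chr>            <dbl> <lgl>
#> 1 P1                1.03 FALSE
```

Without stimulation the task input (c = −12.8%, favoring P2) wins the
competition at 1.78 s; a 10 µA, 300 µs/phase, 200 pps pulse train on P1
reverses the decision and P1 crosses the 15 spk/s threshold at 1.03 s.

Reduced network variants isolate the mechanism — for example, disconnected
P1 neurons measure the direct effect of stimulation without network
feedback:

```r
ve <- variant_experiment("disconnected", "CGS", trials = 20, seed = 1)
median(ve$trials$delta_vs_control)
#> [1] 3.05
```

i.e. −1.4 µA cathodic galvanic current raises the population-averaged task
firing rate of 120 disconnected P1 neurons by ~3 spk/s over the
30.8 spk/s unstimulated mean.

Psychometric experiments chain the same pieces:

```r
plan <- experiment_plan(c("control", "PS"), trials = 20, seed = 1)
results <- run_experiment(plan)
fit <- psychometric_fit(dplyr::filter(results, condition == "PS"))
glance(fit)          # bias (% coherence), sensitivity, counts
autoplot(fit)        # win fraction vs coherence with the fitted curve
```

Canned experiment definitions (`run_canned_experiment()`) reproduce the
headline figures' data tables at full or scaled size, with a JSON manifest
(config hash, seeds, file inventory) that makes each run replayable; a thin
command-line wrapper is available in `scripts/wtastim.R`.

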