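# zebracpg

Spiking-network models of the spinal central pattern generators that drive the
locomotor movements of the developing zebrafish. The package builds and
simulates three developmental circuit models — **single coiling** (~1 day
post-fertilization), **double coiling**, and **beat-and-glide swimming**
(2–3 dpf) — couples them to a simplified musculoskeletal body, and analyzes
the resulting kinematics. It is aimed at computational neuroscientists
studying spinal rhythm generation and at experimentalists who want an
executable testbed for circuit-level hypotheses (which populations drive the
rhythm, what commissural excitation and inhibition contribute, how robust the
output is to parameter variability).

## The model

Every neuron is a single-compartment Izhikevich unit,

    C V' = k (V - Vr)(V - Vt) - u + Isyn
      u' = a (b (V - Vr) - u),        if V >= Vmax:  V <- c, u <- u + d,

integrated with forward Euler at dt = 0.1 ms. Neurons occupy positions along
the rostrocaudal axis (one model somite = 1.6 arbitrary distance units; the
left and right columns sit at y = -1 and y = +1) and are coupled by

* **gap junctions** — ohmic coupling `G (Vpre(t - D/cv) - Vpost)` using the
  delayed presynaptic potential, where D is the Euclidean inter-neuron
  distance and cv the conduction speed;
* **chemical synapses** — dual-exponential conductance kernels
  `W (Vpost - Erev)(e^(-s/tau_r) - e^(-s/tau_f))`, normalized to unit peak and
  re-triggered whenever the (delayed) presynaptic potential rises through
  -15 mV. Glutamatergic synapses reverse at 0 mV; glycinergic synapses
  reverse at -45 / -58 / -70 mV in the three models, tracking the
  developmental hyperpolarization of the chloride potential.

Motoneuron firing drives one muscle cell per somite and side (a passive RC
circuit); the right-left muscle difference forces a chain of uncoupled damped
pendulums whose angles are the local body curvature, from which the midline,
tail displacement, swim episodes, tail-beat frequencies, coil classes, and
left-right alternation statistics are computed.

## Worked example

```r
library(zebracpg)

circ <- build_single_coiling()
circ
#> Spinal circuit model: single_coiling
#>   somites: 10  neurons: 50  connections: 908
#>   populations: IC=10, MN=20, V0d=20
#>   connection kinds: gap=648, gly=260
#>   E_gly: -45 mV, cv: 4 a.d.u./ms

sim <- simulate_circuit(circ, duration = 10000, seed = 1)
summ <- summarize_locomotion(sim)
summ$coil_events[, c("class", "onset", "offset", "duration")]
#>    class onset offset duration
#> 1 single   200   1359     1159
#> 2 single  2070   3125     1055
#> 3 single  3782   4840     1058
#> 4 single  5494   6552     1058
#> 5 single  7207   8263     1056
#> 6 single  8919   9977     1058
```

The ten-somite embryonic circuit, driven by a tonic command to its left
pacemaker (IC) kernel only, generates six evenly interspersed full-body coils
in 10 s — a 0.6 Hz coiling frequency with ~1.06 s coils, matching the
kinematics of real 1-dpf embryos. `plot(sim)` draws the body-angle heat map
(time by segment, red rightward); `plot(sim, "V")` shows membrane traces.

The other factories are `build_double_coiling()` and
`build_beat_and_glide(variant)` with variants `"base"`, `"bursting_v2a"` and
`"all_tonic"`. In-silico experiments mirror the published protocols:

```r
# silence the V2a population during the middle of three 5 s epochs
res <- three_epoch_protocol(build_beat_and_glide("base"),
                            silence_population("V2a", 0, 1), seed = 1)
res$stats          # per-epoch episode/interval/frequency table

# block glycinergic transmission throughout a run
simg <- simulate_circuit(build_beat_and_glide("base"), 10000, seed = 1,
                         perturbations = block_transmitter("glycinergic",
                                                           0, 10000))

# Gaussian parameter-noise sensitivity battery
tab <- run_battery(build_single_coiling, "sigma_p",
                   c(0, 0.01, 0.02, 0.05, 0.1), n_runs = 10,
                   duration = 20000)
```

`run_experiment()` drives everything from a single (YAML-able) configuration
and writes manifest, summary, episode and body-angle files for a fully
reproducible run.

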