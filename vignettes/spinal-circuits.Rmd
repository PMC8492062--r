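---
title: "Modeling the spinal locomotor circuits of developing zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the spinal locomotor circuits of developing zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the models and
their assumptions, the conventions adopted where the published description is
under-determined, the calibration constants and what they were calibrated
against, and the known limitations of the implementation. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The three developmental models

Zebrafish locomotion matures through stereotyped stages: slow single coils of
the whole body around 1 day post-fertilization, double coils (one bend per
side in quick succession) around day 1, and beat-and-glide swimming —
episodes of fast, low-amplitude, left-right alternating tail beats separated
by silent glides — from day 2–3. The package implements one circuit model per
stage, each built from genetically or morphologically identified spinal
populations:

* **Single coiling** (`build_single_coiling()`): a rostral kernel of five
  recurrently gap-coupled, endogenously bursting pacemaker interneurons (ICs)
  per side drives ipsilateral chains of motoneurons (MNs) and commissural
  inhibitory V0d interneurons through electrical synapses. V0ds send
  glycinergic projections to the contralateral MNs (five segments up and
  down) and to all contralateral ICs; at this stage the glycinergic reversal
  potential is depolarized (−45 mV), so these inputs appear as the
  subthreshold synaptic bursts recorded in embryos rather than as functional
  inhibition. Only the left kernel is driven, so all coils form on one side.
* **Double coiling** (`build_double_coiling()`): the same scaffold plus
  commissural excitatory V0vs and ipsilateral descending V2as. V2as are
  recruited through gap junctions with the kernel and excite V0vs through a
  deliberately weak glutamatergic synapse, so V0vs fire late in a coil; V0v
  output onto the *contralateral* ICs then triggers the second, opposite-side
  coil. Glycinergic V0d output (reversal −58 mV) suppresses further
  reverberation so that events stop at two coils. Both kernels are driven,
  the right one 1500 ms later.
* **Beat-and-glide swimming** (`build_beat_and_glide()`): fifteen somites per
  side, no pacemaker kernel. Tonically driven V2as (the rhythm engine)
  excite MNs, commissural dI6s and V0vs, V1s and each other; dI6s supply
  commissural glycinergic inhibition (reversal −70 mV), V0vs delayed
  commissural excitation, and V1s short-range ipsilateral ascending
  inhibition that limits episode vigor and duration. The base variant gives
  V0vs a chattering/bursting parameter set; `"bursting_v2a"` moves the
  bursting phenotype to the V2as, and `"all_tonic"` removes bursting
  entirely.

Every neuron is a nine-parameter Izhikevich unit integrated by forward Euler
at dt = 0.1 ms, with the post-spike reset applied when the membrane reaches
its spike peak; the stored trace is clamped at the peak on the spike sample.
The per-population parameter sets, synaptic weights, reversal potentials,
conduction speeds and drives ship as YAML sheets under
`inst/extdata/params/` and every value can be overridden via the factories'
`overrides` argument (dotted paths, e.g. `"populations.V2a.I_drive"`).

Neurons carry (x, y) coordinates (x rostrocaudal in arbitrary distance
units, 1 somite = 1.6 a.d.u.; y = ±1 for the two sides). Conduction delays
are Euclidean distance over a conduction speed cv of 4.0, 1.0 and
0.8 a.d.u./ms in the three models; at 0.8 the intersegmental delay for a
commissural projection is 3.0–4.0 ms. (The speed is stated in per-second
units in places, but only per-millisecond units reproduce that printed delay
range.)

## Conventions adopted where the description is under-determined

Several elements of the circuit description admit more than one reading, and
some printed formulas are not physically usable as written. The following
conventions are the package's resolutions; each was chosen once, for stated
reasons, and applies uniformly to all three models.

* **Gap-junction current.** The coupling equation as printed,
  `I = Vpre * G`, has no postsynaptic term: at rest (all potentials near
  −60 mV) every junction would inject a large negative current and the
  network has no resting state. The package's default is the conventional
  ohmic difference form `G (Vpre(t − D/cv) − Vpost)`, under which rest is a
  fixed point and activity both propagates and terminates. The literal
  printed form and a rest-referenced presynaptic-deviation form are
  selectable via `simulate_circuit(gap_form =)` for comparison.
* **Chemical kernel normalization.** The dual exponential with rise 0.5 ms
  and fall 1.0 ms peaks at 0.25, silently scaling every synapse by a quarter
  if the weight multiplies the raw kernel. The package treats the tabulated
  weight as the *peak* conductance (kernel normalized to unit peak), the
  common convention in spiking-network simulators. Without it, several
  documented circuit functions (late V0v recruitment, glycinergic control of
  reverberation) are quantitatively unreachable.
* **Event semantics.** Each upward crossing of the release threshold
  (−15 mV, evaluated on the conduction-delayed presynaptic trace) resets the
  kernel clock (renewal; the printed current formula carries a single
  trigger time). The kernel persists after the presynaptic potential falls
  below threshold. The driving force uses the postsynaptic potential at the
  current time (the state is delayed, not the force). All chemical currents
  are forced to zero for the first 50 ms of every run.
* **Gap neighborhoods.** Within a chain, "three nearest rostral and caudal
  neighbors" is read as the three nearest neighbors in total; for the
  MN–V0d cross-chain coupling the description spells out three rostral plus
  three caudal, and that is what is built. The tabulated gap weight is the
  total conductance of a coupled pair.
* **Kernel reach.** The IC kernel's gap junctions extend along the entire
  motoneuron chain rather than only its first four somites: with the
  tabulated pair conductances, chain-to-chain diffusion attenuates within a
  couple of somites and a four-somite kernel reach cannot recruit the caudal
  body (the longer-bodied model variants likewise extend the kernel's axons
  to all somites). IC coupling onto the V0d and V0v chains stays restricted
  to the first four somites as described, which preserves the late-V0v
  mechanism.
* **V2a–IC coupling (double coiling).** Electrical coupling between V2as and
  ICs is restricted to the V2as of the four rostral somites — the neurons
  physically adjacent to the kernel, in parallel with the stated rostral
  restriction of IC–V0v coupling. Coupling all fifteen V2as to the kernel
  locks ICs and V2as in a permanent depolarized plateau and abolishes
  coiling altogether.
* **V2a→V0v weight (double coiling).** The tabulated value 0.04 delivers, under
  any kernel convention, a maximal sustained current roughly two orders of
  magnitude below V0v rheobase, so V0vs could never fire and no double coil
  could depend on glutamate — contradicting the documented behavior of the
  very model the table describes. The package uses 0.4, consistent with the
  V2a→V0v weights of all three swimming variants (0.25–0.3) and with a
  dropped digit in the source table; with it V0vs fire late in the first
  coil and glutamatergic block collapses double coiling, as described.
* **Beat-and-glide projection ranges.** V2a projections are "segmental and
  descending": same-segment targets are included along with segments +1…+6
  (V2a→V2a stays strictly caudal, as stated). V1 projections are "segmental
  and ascending" over segments 0…−2. The V2a→V1 range is not stated; it is
  implemented as local (same segment to +3), keeping the V1 feedback loop
  segmental in line with the short-range character of V1 connectivity.
* **Neuromuscular junction.** MN→muscle transmission uses the standard
  synaptic kernel with the glutamatergic reversal, but the driving force is
  evaluated at a fixed reference (the MN resting potential): the muscle's
  own potential is expressed relative to its rest (0), which coincides with
  the reversal, so a literal conductance synapse onto the muscle would carry
  no current. The muscle cell has no threshold and never spikes.

## Musculoskeletal model and calibration constants

Each somite's muscle cell is a passive RC circuit `V' = −V/(RC) + Isyn/C`
(the printed equation's positive leak is corrected to a decay; R, C = 25, 10
for single coiling, 50, 5 for double coiling, 1, 3 for swimming). The body is
a chain of uncoupled damped pendulums,
`θ'' + 2ζω0 θ' + ω0² θ = g (VR − VL)`, with positive θ rightward; the midline
follows `x_i = x_{i−1} + l cos θ_i`, `y_i = y_{i−1} − l sin θ_i` (the printed
x-recursion uses sin for both coordinates, under which a straight body would
have zero length; x uses the standard cosine). ζ, ω0 and the gain g are not
specified by the source and are calibration constants, chosen once per model
and never varied between conditions:

* ζ = 1 (critical damping, no mechanical ringing beyond the drive),
* ω0 = 0.8 rad/ms (bandwidth above the fastest synaptic drive, so the body
  tracks the neural command),
* g = 2.5 (single coiling), 1.4 (double coiling and swimming), set so that a
  single coil is a large unilateral bend of roughly one second and swimming
  beats are low-amplitude.

The analysis constants are likewise declared calibrations: swim episodes are
detected at 0.5 units on the integrated motor output (the muscle-cell sum of
both sides convolved with a unit-amplitude 50 ms boxcar); tail beats are
midline crossings of the most caudal body point at ±0.5 a.d.u., with
intervals over 100 ms discarded as inter-episode; the left-right alternation
index is the minimum of the normalized (non-mean-subtracted) left-right
cross-correlation over lags ±10 ms (±20 ms selectable). The coil classifier —
the source never prints one — marks a coil candidate where one side's body
angle exceeds 0.2 rad, calls it full if the bend covers at least two-thirds
of the body, chains consecutive opposite-side full coils with onsets within
1000 ms into double/multiple events, and reports the rest as single or
truncated. The 0.2 rad amplitude threshold and the body gains were fixed
together against one anchor: the base single-coiling run must produce six
single full coils of about one second in ten seconds. Events still above
threshold when a recording ends are flagged `censored` and excluded from
duration averages. The first 200 ms of every simulation are excluded from all
analyses.

## Noise, perturbations, and reproducibility

The sensitivity machinery multiplies parameters by independent Gaussian(1, σ)
draws: σd scales the tonic command freshly at every time step inside the
engine; σp scales each of the nine membrane parameters of every neuron once
at initialization (signed); σw (or the chemical-only / gap-only variants)
scales every synaptic weight once (clamped at zero); σl scales each
projection rule's rostrocaudal extents per neuron, rounded to whole segments,
with target sets and delays rebuilt. Batteries only vary one σ at a time, per
the study design; the noisy double-coiling condition (σd = 0.5, σp = 0.01,
σw = 0.05 simultaneously) is the stated exception. The dI6→contralateral-dI6
weights always carry Gaussian(1, 0.1) scaling (standard deviation, following
the prose over a footnote that says "variance") — the symmetry-breaking
required for left-right alternation: the noise-free model is exactly
symmetric and swims with synchronous left-right output.

Silencing a population removes all synaptic and external currents from its
members (gap-junction input included by default, excludable via
`silence_includes_gap`); membrane dynamics keep running, and outgoing
synapses fall silent because the neurons stop firing. Transmitter blockade
zeroes all currents of one chemical class; gap junctions and the
neuromuscular junction are unaffected. `three_epoch_protocol()` runs the
intact–perturbed–restored design with episodes detected on the full run and
assigned to epochs by their midpoints, so bouts spanning an epoch boundary
are counted once.

One global RNG stream (R's, via `set.seed`) governs each experiment, consumed
in a fixed order: build-time weight noise, then parameter noise, then length
noise, then the per-step drive noise inside the engine. Identical seed,
model, and duration give bit-identical results; the batteries derive one
sub-seed per run.

## Problem sizes used by the shipped analyses

The reproduction script and the acceptance-level tests use the study-scale
designs: one 10 s single-coiling run; five 100 s double-coiling runs under
the noisy condition; ten 10 s beat-and-glide runs; three-epoch protocols of
3 × 5 s. Unit and property tests use seconds-long runs and two-neuron toy
circuits with brute-force oracles for the delayed-kernel and Euler
arithmetic.

## Known limitations

* The double-coiling model, under the conventions above, produces genuine
  glutamate-dependent double coils, but at roughly 20–25 % of events rather
  than a ~60 % majority: the side that generates a coil keeps its V0d chain
  firing beyond the coil (nothing inhibits V0ds, and their excitable
  parameter set sustains them), and the lingering commissural inhibition
  clamps the contralateral kernel through part of the trigger window. The
  pharmacological directions (glutamate block collapses doubles, glycine
  block promotes chained events) are nevertheless reproduced.
* The beat-and-glide model's episode duration and inter-episode interval fall
  in the documented range, but its within-episode left-right alternation is
  locked to the commissural loop delays (~11 ms, i.e. ~85–90 Hz) rather than
  the documented 20–60 Hz tail-beat band. A slower network rhythm would
  require either weaker effective synaptic efficacies than the kernel
  convention yields or additional dynamics (e.g. slower synaptic time
  constants for inhibition) that the source tables do not specify.
* The 30-somite variants reuse the base gap weights (the retuned values are
  not published); every weight is overridable for users who wish to retune.
* The models emulate intact-network dynamics only: no sensory input, no
  hydrodynamics or inter-segment mechanical coupling, no neuromodulation,
  and point neurons without specific ionic conductances. Passing tests show
  that the implementation reproduces the documented *model* behaviors at the
  stated scales, not that the models capture any particular property of real
  fish beyond those behaviors.
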