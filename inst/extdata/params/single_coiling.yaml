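# Single coiling model (~17+ hpf): IC pacemaker kernel + MN and V0d chains.
# All membrane parameters follow the published parameter tables for this stage.
name: single_coiling
constants:
  E_gly: -45.0      # mV, depolarized chloride reversal at this stage
  E_glut: 0.0       # mV
  tau_r: 0.5        # ms, synaptic rise time constant
  tau_f: 1.0        # ms, synaptic fall time constant
  V_thr: -15.0      # mV, presynaptic release threshold
  cv: 4.0           # a.d.u./ms, axonal conduction speed
  dt: 0.1           # ms, Euler time step
  somite_length: 1.6  # a.d.u.
  chem_off_ms: 50.0   # chemical synapses disabled for this initial window
  gap_pair_junctions: 1  # junction instances per coupled pair; the table
                         # weight is the total pair conductance
populations:
  IC:
    a: 0.0005
    b: 0.5
    c: -30.0
    d: 5.0
    Vmax: 0.0
    Vr: -60.0
    Vt: -45.0
    k: 0.05
    C: 50.0
    x_offset: 1.0
    x_step: 0.0       # rostral kernel: all ICs share x = 1.0
    count: 5
    I_drive: 50.0
    drive_onset: {left: 0.0, right: .inf}   # tonic command to left ICs only
  MN:
    a: 0.5
    b: 0.1
    c: -50.0
    d: 0.2
    Vmax: 10.0
    Vr: -60.0
    Vt: -45.0
    k: 0.05
    C: 20.0
    x_offset: 5.0
    x_step: 1.6
    count: 10
    I_drive: 0.0
  V0d:
    a: 0.5
    b: 0.01
    c: -50.0
    d: 0.2
    Vmax: 10.0
    Vr: -60.0
    Vt: -45.0
    k: 0.05
    C: 20.0
    x_offset: 5.0
    x_step: 1.6
    count: 10
    I_drive: 0.0
gap_weights:
  MN-MN: 0.1
  IC-MN: 0.04
  IC-IC: 0.001
  V0d-MN: 0.01
  V0d-IC: 0.05
  V0d-V0d: 0.04
chem_weights:
  V0d-MN: 0.3    # glycinergic, contralateral, i-5..i+5
  V0d-IC: 0.3    # glycinergic, contralateral, all ICs
  MN-Muscle: 0.015
muscle:
  R: 25.0
  C: 10.0
  somites_per_muscle: 3
body:
  zeta: 1.0         # critically damped pendulums
  omega0: 0.8       # rad/ms natural frequency; bandwidth above the drive band
  gain: 2.5         # forcing gain, calibrated for a full coil lasting ~1 s
  segment_length: 1.6
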