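# Double coiling model (~24+ hpf): coiling scaffold + commissural excitatory V0vs
# and ipsilateral descending V2as forming a hybrid electrical-chemical circuit.
name: double_coiling
constants:
  E_gly: -58.0
  E_glut: 0.0
  tau_r: 0.5
  tau_f: 1.0
  V_thr: -15.0
  cv: 1.0
  dt: 0.1
  somite_length: 1.6
  chem_off_ms: 50.0
  gap_pair_junctions: 1  # junction instances per coupled pair; the table
                         # weight is the total pair conductance
populations:
  IC:
    a: 0.0002
    b: 0.5
    c: -40.0
    d: 5.0
    Vmax: 0.0
    Vr: -60.0
    Vt: -45.0
    k: 0.03
    C: 50.0
    x_offset: 1.0
    x_step: 0.0
    count: 5
    I_drive: 35.0
    drive_onset: {left: 0.0, right: 1500.0}  # right command delayed by 1500 ms
  MN:
    a: 0.5
    b: 0.1
    c: -50.0
    d: 100.0
    Vmax: 10.0
    Vr: -60.0
    Vt: -50.0
    k: 0.05
    C: 20.0
    x_offset: 5.0
    x_step: 1.6
    count: 10
    I_drive: 0.0
  V0d:
    a: 0.02
    b: 0.1
    c: -30.0
    d: 3.75
    Vmax: 10.0
    Vr: -60.0
    Vt: -45.0
    k: 0.09
    C: 6.0
    x_offset: 5.0
    x_step: 1.6
    count: 10
    I_drive: 0.0
  V0v:
    a: 0.02
    b: 0.1
    c: -30.0
    d: 11.6
    Vmax: 10.0
    Vr: -60.0
    Vt: -45.0
    k: 0.05
    C: 20.0
    x_offset: 5.1
    x_step: 1.6
    count: 10
    I_drive: 0.0
  V2a:
    a: 0.5
    b: 0.1
    c: -40.0
    d: 100.0
    Vmax: 10.0
    Vr: -60.0
    Vt: -45.0
    k: 0.05
    C: 20.0
    x_offset: 5.1
    x_step: 1.6
    count: 10
    I_drive: 0.0
gap_weights:
  MN-MN: 0.07
  IC-MN: 0.03
  IC-IC: 0.0001
  V0d-MN: 0.0001
  V0d-IC: 0.05
  V0d-V0d: 0.04
  V0v-MN: 0.0001
  V0v-IC: 0.0005
  V0v-V0v: 0.05
  V2a-MN: 0.005
  V2a-IC: 0.15
  V2a-V2a: 0.005
chem_weights:
  V0d-MN: 2.0    # glycinergic, contralateral, i-5..i+5
  V0d-IC: 2.0    # glycinergic, contralateral, all ICs
  V0d-V2a: 2.0   # glycinergic, contralateral, i-5..i+5
  V0v-IC: 0.175  # glutamatergic, contralateral, all ICs (second-coil trigger)
  V2a-V0v: 0.4   # glutamatergic, ipsilateral, same segment +/- 3; the
                 # delayed-excitation link that recruits V0vs late in a coil
  MN-Muscle: 0.02
muscle:
  R: 50.0
  C: 5.0
  somites_per_muscle: 3
body:
  zeta: 1.0
  omega0: 0.8
  gain: 1.4
  segment_length: 1.6
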