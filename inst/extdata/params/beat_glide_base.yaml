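# Beat-and-glide swimming, base model (2-3+ dpf): network oscillator with no
# pacemaker kernel; V2as drive the rhythm, V0vs burst, dI6/V1 are glycinergic.
name: beat_glide_base
constants:
  E_gly: -70.0
  E_glut: 0.0
  tau_r: 0.5
  tau_f: 1.0
  V_thr: -15.0
  cv: 0.8
  dt: 0.1
  somite_length: 1.6
  chem_off_ms: 50.0
  gap_pair_junctions: 1  # junction instances per coupled pair; the table
                         # weight is the total pair conductance
populations:
  MN:
    a: 0.5
    b: 0.01
    c: -55.0
    d: 100.0
    Vmax: 10.0
    Vr: -65.0
    Vt: -58.0
    k: 0.5
    C: 20.0
    x_offset: 5.0
    x_step: 1.6
    count: 15
    I_drive: 0.0
  dI6:
    a: 0.1
    b: 0.002
    c: -55.0
    d: 4.0
    Vmax: 10.0
    Vr: -60.0
    Vt: -54.0
    k: 0.3
    C: 10.0
    x_offset: 5.1
    x_step: 1.6
    count: 15
    I_drive: 0.0
  V0v:
    a: 0.01
    b: 0.002
    c: -55.0
    d: 8.0
    Vmax: 10.0
    Vr: -60.0
    Vt: -54.0
    k: 0.3
    C: 10.0
    x_offset: 5.1
    x_step: 1.6
    count: 15
    I_drive: 0.0
  V2a:
    a: 0.1
    b: 0.002
    c: -55.0
    d: 4.0
    Vmax: 10.0
    Vr: -60.0
    Vt: -54.0
    k: 0.3
    C: 10.0
    x_offset: 5.1
    x_step: 1.6
    count: 15
    I_drive: 2.89
    drive_onset: {left: 0.0, right: 0.0}   # bilateral tonic command
  V1:
    a: 0.1
    b: 0.002
    c: -55.0
    d: 4.0
    Vmax: 10.0
    Vr: -60.0
    Vt: -54.0
    k: 0.3
    C: 10.0
    x_offset: 7.1     # V1s run from segment 2 to the caudal end
    x_step: 1.6
    count: 15
    I_drive: 0.0
gap_weights:
  MN-MN: 0.005
  dI6-MN: 0.0001
  dI6-dI6: 0.04
  V0v-MN: 0.005
  V0v-V0v: 0.05
  V2a-MN: 0.005
  V2a-V2a: 0.005
chem_weights:
  dI6-MN: 1.5     # glycinergic, contralateral, asc i-1 / desc i+1..i+3
  dI6-dI6: 0.25   # glycinergic, contralateral; per-connection Gaussian(1, 0.1) scale
  dI6-V2a: 1.5    # glycinergic, contralateral
  V0v-V2a: 0.4    # glutamatergic, contralateral, asc i-1 / desc i+1..i+3
  V2a-MN: 0.5     # glutamatergic, ipsilateral, desc i+1..i+6 and asc i-1..i-2
  V2a-dI6: 0.5    # glutamatergic, ipsilateral, desc i+1..i+6
  V2a-V0v: 0.3    # glutamatergic, ipsilateral, desc i+1..i+6 and asc i-1..i-2
  V2a-V2a: 0.3    # glutamatergic, ipsilateral, desc i+1..i+6
  V2a-V1: 0.5     # glutamatergic, ipsilateral, desc i+1..i+6
  V1-MN: 1.0      # glycinergic, ipsilateral, rostral i-1..i-2
  V1-dI6: 0.2     # glycinergic, ipsilateral, rostral i-1..i-2
  V1-V0v: 0.1     # glycinergic, ipsilateral, rostral i-1..i-2
  V1-V2a: 0.5     # glycinergic, ipsilateral, rostral i-1..i-2
  MN-Muscle: 0.1
dI6_noise_sd: 0.1
muscle:
  R: 1.0
  C: 3.0
  somites_per_muscle: 2
body:
  zeta: 1.0
  omega0: 0.8
  gain: 1.4
  segment_length: 1.6
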