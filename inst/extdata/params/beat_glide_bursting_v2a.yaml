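# Beat-and-glide swimming, bursting-V2a variant: V2as burst, V0vs fire tonically;
# V2a output weights reduced, commissural weights onto V2as increased.
name: beat_glide_bursting_v2a
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
  V2a:
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
    I_drive: 3.05
    drive_onset: {left: 0.0, right: 0.0}
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
    x_offset: 7.1
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
  dI6-MN: 1.5
  dI6-dI6: 0.25
  dI6-V2a: 2.0
  V0v-V2a: 0.75
  V2a-MN: 0.5
  V2a-dI6: 0.75
  V2a-V0v: 0.275
  V2a-V2a: 0.3
  V2a-V1: 0.5
  V1-MN: 1.0
  V1-dI6: 0.2
  V1-V0v: 0.1
  V1-V2a: 0.5
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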