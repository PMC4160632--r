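name: stenfelt2002_dry_skull
geometry:
  kind: shell
  outer_radius: 0.08
  refinement_level: 3.0
  layers_bone: 3.0
  layers_lining: 2.0
  target_bone_mass: 0.47
  target_lining_mass: 0.34
  calibrate: yes
materials:
  bone:
    E1: 7.3e+09
    nu: 0.3
    rho: 870.23
    loss:
      kind: constant
      eta0: 0.01
  polyurethane:
    E1: 1000000.0
    nu: 0.33
    rho: 997.4
    loss:
      kind: linear_in_f
      alpha_f: 0.0001
load:
  node_set: stim_site
  direction:
  - 1.0
  - 0.0
  - 0.0
  amplitude: 1.0e-06
grid:
  'n': 60.0
  f_min: 100.0
  f_max: 10000.0
probes:
  ipsi: ipsi_cochlea
  contra: contra_cochlea
fields:
  frequencies:
  - 100.0
  - 600.0
  phases_deg:
  - 0.0
  - 180.0
  variants: no
variants:
- name: re_x100
  region: polyurethane
  set:
    E1: 1.0e+08
    eta0: 0.0001
- name: re_d100
  region: polyurethane
  set:
    E1: 10000.0
    eta0: 1.0
- name: im_x100
  region: polyurethane
  set:
    eta0: 1.0
- name: im_d100
  region: polyurethane
  set:
    eta0: 0.0001
- name: rho_low
  region: polyurethane
  set:
    rho: 99.74
- name: rho_x10
  region: polyurethane
  scale:
    rho: 10.0
- name: heavy_head
  region: polyurethane
  set:
    rho: 8800.0
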