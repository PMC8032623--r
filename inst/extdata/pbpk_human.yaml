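# Whole-body permeability-limited PBPK parameter set: human, 73 kg
# reference subject, amiodarone.
#
# SYNTHETIC / REPRESENTATIVE FIXTURE. Physiological volumes and blood
# flows are standard reference-man values; compound parameters (unbound
# fractions, PS products, hepatic clearance) are representative
# literature-style values for a highly protein-bound, lipophilic drug.
# The brain PS product is calibrated so that the simulated day-14 brain
# extravascular AUC(0-24) per unit dose reproduces published amiodarone
# reverse-dosimetry dose scaling; it is a calibration constant, not a
# measured permeability.
description: >-
  Representative human amiodarone parameterization (synthetic fixture;
  brain PS calibrated to published reverse-dosimetry dose scaling).
species: human
units:
  volumes: L
  flows: L/h
  PS: L/h
  clearance: L/h
  body_weight: kg
body_weight: 73
cardiac_output: 390.0
blood_volumes:
  venous: 3.4
  arterial: 1.8
lung:
  volume_vascular: 0.15
  volume_tissue: 0.5
  PS: 100
  fu_tissue: 0.02
hepatic_clearance: 8
compound:
  molecular_weight: 645.31
  fu_plasma: 0.06
  blood_plasma_ratio: 0.73
tissues:
  - {name: brain,   volume_vascular: 0.07, volume_tissue: 1.45, blood_flow: 46.8, PS: 0.00032, fu_tissue: 0.02}
  - {name: heart,   volume_vascular: 0.03, volume_tissue: 0.33, blood_flow: 15.6, PS: 20,   fu_tissue: 0.02}
  - {name: liver,   volume_vascular: 0.30, volume_tissue: 1.80, blood_flow: 25.4, PS: 60,   fu_tissue: 0.02}
  - {name: kidney,  volume_vascular: 0.06, volume_tissue: 0.31, blood_flow: 74.1, PS: 40,   fu_tissue: 0.02}
  - {name: muscle,  volume_vascular: 0.80, volume_tissue: 29.0, blood_flow: 66.3, PS: 50,   fu_tissue: 0.02}
  - {name: skin,    volume_vascular: 0.15, volume_tissue: 3.30, blood_flow: 19.5, PS: 15,   fu_tissue: 0.02}
  - {name: adipose, volume_vascular: 0.20, volume_tissue: 18.0, blood_flow: 19.5, PS: 10,   fu_tissue: 0.02}
  - {name: gut,     volume_vascular: 0.15, volume_tissue: 1.10, blood_flow: 58.5, PS: 30,   fu_tissue: 0.02}
  - {name: spleen,  volume_vascular: 0.03, volume_tissue: 0.15, blood_flow: 11.7, PS: 8,    fu_tissue: 0.02}
  - {name: rest,    volume_vascular: 0.20, volume_tissue: 7.00, blood_flow: 52.6, PS: 20,   fu_tissue: 0.02}
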