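# Whole-body permeability-limited PBPK parameter set: rat, 250 g,
# amiodarone.
#
# SYNTHETIC / REPRESENTATIVE FIXTURE. Physiology is standard rat
# reference values; compound parameters are the human fixture's values
# scaled down roughly with body size. Used for the rat branch of the
# analysis (oral bioavailability F = 0.35); not calibrated against any
# measured rat data.
description: >-
  Representative rat amiodarone parameterization (synthetic fixture).
species: rat
units:
  volumes: L
  flows: L/h
  PS: L/h
  clearance: L/h
  body_weight: kg
body_weight: 0.25
cardiac_output: 4.98
blood_volumes:
  venous: 0.0105
  arterial: 0.0055
lung:
  volume_vascular: 0.0005
  volume_tissue: 0.0012
  PS: 0.33
  fu_tissue: 0.02
hepatic_clearance: 0.027
compound:
  molecular_weight: 645.31
  fu_plasma: 0.06
  blood_plasma_ratio: 0.73
tissues:
  - {name: brain,   volume_vascular: 0.0001,  volume_tissue: 0.0017, blood_flow: 0.10, PS: 0.0000011, fu_tissue: 0.02}
  - {name: heart,   volume_vascular: 0.0001,  volume_tissue: 0.0010, blood_flow: 0.25, PS: 0.07,  fu_tissue: 0.02}
  - {name: liver,   volume_vascular: 0.0011,  volume_tissue: 0.0103, blood_flow: 0.10, PS: 0.20,  fu_tissue: 0.02}
  - {name: kidney,  volume_vascular: 0.0002,  volume_tissue: 0.0020, blood_flow: 0.70, PS: 0.13,  fu_tissue: 0.02}
  - {name: muscle,  volume_vascular: 0.0027,  volume_tissue: 0.1220, blood_flow: 1.39, PS: 0.17,  fu_tissue: 0.02}
  - {name: skin,    volume_vascular: 0.0005,  volume_tissue: 0.0430, blood_flow: 0.30, PS: 0.05,  fu_tissue: 0.02}
  - {name: adipose, volume_vascular: 0.0007,  volume_tissue: 0.0170, blood_flow: 0.35, PS: 0.03,  fu_tissue: 0.02}
  - {name: gut,     volume_vascular: 0.0005,  volume_tissue: 0.0110, blood_flow: 0.75, PS: 0.10,  fu_tissue: 0.02}
  - {name: spleen,  volume_vascular: 0.0001,  volume_tissue: 0.0006, blood_flow: 0.05, PS: 0.027, fu_tissue: 0.02}
  - {name: rest,    volume_vascular: 0.0007,  volume_tissue: 0.0200, blood_flow: 0.99, PS: 0.07,  fu_tissue: 0.02}
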