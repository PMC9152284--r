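name: b2
V0: 4.0
c_x0: 0.21
c_gluc0: 30.0
c_nano30: 3.0
t_growth_end: 48.0
t_end: 333.0
dt_growth: 0.05
dt_production: 0.2
use_total_biomass: no
seed: 1
oil_feeds:
- kind: bolus
  t_start: 48.0
  t_end: 48.0
  frac_vv: 6.0
  reference_volume: 4.0
  oil_density: 0.92
- kind: bolus
  t_start: 118.0
  t_end: 118.0
  frac_vv: 4.0
  reference_volume: 4.0
  oil_density: 0.92
- kind: bolus
  t_start: 165.0
  t_end: 165.0
  frac_vv: 4.0
  reference_volume: 4.0
  oil_density: 0.92
- kind: bolus
  t_start: 215.0
  t_end: 215.0
  frac_vv: 4.0
  reference_volume: 4.0
  oil_density: 0.92
- kind: bolus
  t_start: 286.0
  t_end: 286.0
  frac_vv: 4.0
  reference_volume: 4.0
  oil_density: 0.92
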