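cost_schedule:
  items:
    '111':
      cost: 7.33
      unit: call
    '999':
      cost: 7.33
      unit: call
    ED1A:
      cost: 262.57
      unit: attendance
    ED1NA:
      cost: 170.66
      unit: attendance
    ED2A:
      cost: 142.26
      unit: attendance
    ED2NA:
      cost: 109.92
      unit: attendance
    ED3A:
      cost: 115.69
      unit: attendance
    ED3NA:
      cost: 73.57
      unit: attendance
    ED4A:
      cost: 44.17
      unit: attendance
    ED4NA:
      cost: 45.71
      unit: attendance
    GP:
      cost: 39.0
      unit: consultation
    HA:
      cost: 1215.74
      unit: episode
    HS2_admin:
      cost: 2.55
      unit: minute
    HS2_booklet:
      cost: 1.6
      unit: booklet
    HTR:
      cost: 47.49
      unit: patient
    STC:
      cost: 257.34
      unit: incident
    STR:
      cost: 209.38
      unit: incident
self_manage:
  read_action:
  - 0.08125
  - 0.08125
  - 0.01875
  - 0.01875
  - 0.8
  other:
  - 0.10625
  - 0.10625
  - 0.03125
  - 0.03125
  - 0.725
state_costs:
  intervention:
    cost: 9.95
    provider: ems
  gp_consult:
    cost: 39.0
    provider: primary
  call_999:
    cost: 7.33
    provider: ems
  call_111:
    cost: 7.33
    provider: iuc
  redirect_999:
    cost: 7.33
    provider: iuc
  htr:
    cost: 47.49
    provider: ems
  pathways_111:
    cost: 71.94
    provider: iuc
  self_manage:
    provider: secondary
  stc:
    cost: 257.34
    provider: ems
  str:
    cost: 209.38
    provider: ems
  ed_ha:
    cost: 1478.13
    provider: secondary
  ed:
    cost: 168.89
    provider: secondary
attribution:
  pathways_111: iuc
transitions:
  hs2:
    stage1:
    - 0.4125
    - 0.3375
    - 0.25
    rates:
    - 0.75
    - 0.9
    - 1.0
    p31:
    - 0.3625
    - 0.4
    - 0.4
    p32:
    - 0.2375
    - 0.35
    - 0.35
    observed_repeat_rate: 0.045
  sc:
    stage1:
    - 0.25
    - 0.75
    rates:
    - 0.75
    - 1.0
    p31:
    - 0.4
    - 0.4
    p32:
    - 0.35
    - 0.35
    observed_repeat_rate: 0.055
  convey: 0.6
  admit: 0.333333333333
  r_max: 1.65
utilities:
  u0: 0.8
  decrements:
  - 0.004
  - 0.007
  - 0.062
  - 0.057
  day_share: 0.28
  annualisation_factor: 0.049450549451
  t_dist:
  - 0.0
  - 14.0
  - 2.0
  alt_decrements:
  - 0.014
  - 0.047
  use_alt_decrements: no
population:
  annual_attendances: 7900000.0
  hypo_call_rate: 0.006
  repeat_fraction: 0.05
  convey_fraction: 0.6
trial:
  hs2:
  - 32.0
  - 707.0
  sc:
  - 92.0
  - 1674.0
  day_share: 0.28
  convey_p: 0.6
  added_minutes:
  - 6.6
  - 2.0
psa:
  n_sims: 10000.0
  rate_support:
  - 0.0
  - 1.65
  rate_modes:
  - 0.75
  - 0.9
  - 1.0
  enforce_rate_ordering: no
costmin:
  pgp:
  - 0.3
  - 0.4
  - 0.5
  max_cycles: 6.0
  absorption_threshold: 0.95
  absorbed_accrual: none
  n_sims: 10000.0
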