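# Whole-community parameterization: 110 reproductively mature members,
# 50% female dispersal, male philopatry, fully local mating; replacement
# 0.076 per 2.5-year timestep (2.5 / 32.8-year mean lifespan).
params:
  n_females: 66
  n_males: 44
  disp_f: 0.5
  disp_m: 0.0
  repl_f: 0.076
  repl_m: 0.076
  local_mating: 1.0
  n_steps: 30
  step_years: 2.5
  maturity_age_f: 13
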