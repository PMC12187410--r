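# Typical mixed-sex association subgroup: 30 members at the observed 60%
# female share; high female (0.9) and low male (0.1) dispersal across
# subgroup boundaries, fully local mating.
params:
  n_females: 18
  n_males: 12
  disp_f: 0.9
  disp_m: 0.1
  repl_f: 0.076
  repl_m: 0.076
  local_mating: 1.0
  n_steps: 30
  step_years: 2.5
  maturity_age_f: 13
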