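# Obesity population dynamics for the region of Valencia, Spain.
# Body-mass-index compartments as population proportions, time in weeks
# (t = 0 is the year-2000 health survey). The reduced variant integrates
# the overweight (S) and obese (O) equations and closes normal weight as
# N = 1 - S - O.
model: obesity
variant: reduced

# Transmission/transition rates per week. The four transmission parameters
# carry sampling uncertainty and are modeled Uniform(0, 2 * estimate), so
# each mean equals its survey point estimate; demographic turnover mu is
# treated as known.
parameters:
  beta: {dist: uniform_about, mean: 0.00085}
  gamma: {dist: uniform_about, mean: 0.0003}
  epsilon: {dist: uniform_about, mean: 0.000004}
  rho: {dist: uniform_about, mean: 0.000035}
  mu: 0.000469

chaos:
  order: 2

time:
  t_end: 800
  stride: 4

analyses: [deterministic, chaos, sobol]
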