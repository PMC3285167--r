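# Reference steering protocol: 30 replicates x 2,000,000 steps (0.5 fs/step,
# 1 ns each), snapshots from a restrained 1 ns pre-run, CV steered right-to-
# left with a stiff spring, samples every 2.5 ps. The model landscape is a
# double well whose minima sit at the two CV endpoints.
system:
  name: quartic_double_well
  temperature: 300
  parameters:
    V0: 3.0
    center: 6.22
    half_width: 2.70
cv:
  pairs:
  - [1, 2]
  coefficients: [1.0]
protocol:
  control: cv
  k: 1000.0
  lambda0: 8.92
  lambda1: 3.52
  n_steps: 2000000
  dt: 0.0005
  n_replicates: 30
  seed_base: 0
  snapshot_interval: 60000
  snapshot_run_steps: 2000000
  sample_interval: 5000
analysis:
  n_boot: 3000
output:
  dir: paper_protocol_out
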