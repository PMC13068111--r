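# Demonstration pipeline: simulate a small clean cohort, train the densely
# connected model and a single-block baseline, evaluate on held-out subjects
# and compare. Desk-scale sizes; finishes in minutes on one CPU.
seed: 7
out_dir: demo-results
simulate:
  n_subjects: 8
  preset: clean
  duration_s: 90
pipeline:
  working_fs: 125
  segment_len: 512
  train_stride: 256
  eval_stride: 512
model:
  n_blocks: 5
  hidden_units: 6
  connection: dense
baseline:
  n_blocks: 1
  hidden_units: 6
  connection: single
train:
  epochs: 25
  batch_size: 32
  learning_rate: 0.003
split:
  val_fraction: 0.25
  test_fraction: 0.25
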