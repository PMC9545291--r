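# Study-scale configuration shared by the numbered analysis scripts.
# Entries override the defaults of oddballerp::pipeline_config().
seed: 1
cohort:
  n_animals: 14
  trial_noise_sd: 1.0
  animal_effect_sd: 0.1
  alpha_amplitude: 0.2
decoding:
  folds: 10
  repeats: 5
stats:
  n_perm: 1000
  alpha: 0.05
model:
  epochs: 500
  n_models: 5
  batch_size: 32
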