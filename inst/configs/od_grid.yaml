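# Hyperparameter grid for odor-descriptor prediction, with the best-found
# setting marked. Loop over the grid with the CLI `train` subcommand.
grid:
  n_heads: [6, 8, 10, 12]
  head_dim: [30, 50]
  n_encoder_layers: [5, 6, 7, 8]
  n_decoder_layers: [1, 2]
  tau: [0.3, 0.7, 1.0]
best:
  n_heads: 8
  head_dim: 30
  n_encoder_layers: 7
  n_decoder_layers: 2
  tau: 0.7
  learning_rate: 7.0e-5
  dropout: 0.1
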