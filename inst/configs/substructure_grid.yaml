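# Hyperparameter grid for the substructure-prediction experiment:
# 12 heads x 15 dims, 6 encoder layers, 1-4 decoder layers.
common:
  n_heads: 12
  head_dim: 15
  n_encoder_layers: 6
  learning_rate: 7.0e-5
  dropout: 0.1
grid:
  n_decoder_layers: [1, 2, 3, 4]
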