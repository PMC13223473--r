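# Full-scale training recipe (GPU-scale; not exercised in CI).
# 200 epochs, batch size 4, initial learning rate 1e-3 with linear decay,
# AdamW with weight decay 5.17e-4, swarm-optimized loss weights.
config <- list(
  epochs = 200L,
  batch_size = 4L,
  lr0 = 1e-3,
  optimizer = "adamw",
  weight_decay = 5.17e-4,
  model = list(variant = "enhanced", base_channels = 64L)
)
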