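# Example training configuration for the command-line interface.
# Reference-scale settings; shrink ngf/ndf/n_res and epochs for CPU runs.
variant: sfcgan
epochs: 200
batch_size: 4
lr: 0.0002
lr_constant_epochs: 100
lr_decay_epochs: 100
buffer_capacity: 50
seed: 1
ngf: 64
ndf: 64
n_res: 9
checkpoint_every: 50
ssim:
  c1: 0.0001
  c2: 0.009
  window: 11
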