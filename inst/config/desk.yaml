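# desk-scale preset: CPU-sized backbone and schedule
lambda_s: 1.0
lambda_u: 1.0
warmup_epochs: 4
heads_only_epochs: 2
main_epochs: 90
light_main_epochs: 36
lr_warmup: 3.0e-3
lr_heads_only: 3.0e-3
lr_main: 3.0e-3
lr_decay: 1.0
batch_size: 60
ratio: 0.5
repetitions: 3
batches_per_epoch: 25
input_size: 16
channels: [12, 24, 36, 48]
input: rgb
pretrained: null
head_copies: 5
k_over: 30
augmentation: auto
eps: 1.0e-6
val_max: 600
eval_every: 2
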