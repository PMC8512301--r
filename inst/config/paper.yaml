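# full-scale schedule (500 warm-up + 500 main epochs, 100 heads-only,
# Adam 1e-4 with 1e-3 for the heads-only phase, batch ratio r = 0.5,
# 3 repetitions, 5 head copies); backbone remains the built-in CNN,
# sized up to 64 px input
lambda_s: 1.0
lambda_u: 1.0
warmup_epochs: 500
heads_only_epochs: 100
main_epochs: 500
light_main_epochs: 500
lr_warmup: 1.0e-4
lr_heads_only: 1.0e-3
lr_main: 1.0e-4
lr_decay: 1.0
batch_size: 60
ratio: 0.5
repetitions: 3
batches_per_epoch: null
input_size: 64
channels: [16, 32, 48, 64]
input: rgb
pretrained: null
head_copies: 5
k_over: null
augmentation: auto
eps: 1.0e-6
val_max: null
eval_every: 1
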