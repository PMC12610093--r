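# example configuration for `eegcca train --train-config`
epochs: 12
learning_rate: 0.001
lr_step: 3
lr_gamma: 0.5
batch_size: 32
seed: 1
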