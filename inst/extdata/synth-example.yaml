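# example configuration for `eegcca simulate`
n_classes: 4
n_channels: 8
n_timepoints: 256
sampling_rate: 256
trials_per_class: 25
snr: 10
coupling: 1
seed: 1
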