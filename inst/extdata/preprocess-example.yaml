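# example configuration for `eegcca preprocess`
bandpass_low: 0.5
bandpass_high: 100
notch_freq: 50
filter_order: 4
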