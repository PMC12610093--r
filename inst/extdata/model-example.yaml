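# example model overrides for `eegcca train` (geometry comes from the data)
k: 16
h: 4
fusion: cca
variant: full
dropout: 0.3
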