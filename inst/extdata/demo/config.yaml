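corr_threshold: 0.7
min_support: 0.25
mode: clique
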