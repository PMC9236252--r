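# Neuronal (CDT_N) configuration: Table-of-rates defaults, no overrides.
variant: neuronal
horizon: 300
step: 0.1
seed: 1
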