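population,habitat
WF1,forest
WF2,forest
WE1,ecotone
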