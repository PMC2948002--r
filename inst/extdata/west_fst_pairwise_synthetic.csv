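,WF1,WF2,WE1
WF1,0,0.041,0.053
WF2,0.041,0,0.063
WE1,0.053,0.063,0
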