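[0.351,0.074,0.156,0.419]
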