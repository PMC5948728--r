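name: TthHB27I
recognition: CAARCA
top_offset: 11
bottom_offset: 9
overhang: 2
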