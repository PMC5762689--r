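preset: region1
v_r: 0.33
d: 0.01
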