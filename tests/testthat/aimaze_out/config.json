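{"gen":"8x8","density":0.35,"seed":1,"searches":4,"novel":false,"out":"aimaze_out"}
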