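older
younger
twin
half
step
little
big
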