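# non-lung cancer diagnostic groups
G002
G003
G004
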