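CCL5
CXCL10
CXCR2
IL2
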