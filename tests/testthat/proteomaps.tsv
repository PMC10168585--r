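enzyme_protein	0.4
ribosome_protein	0.4
housekeeping_protein	0.19999999999999993
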