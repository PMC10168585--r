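kind,id,value
flux,R_uptake,0.8000000000000004
enzyme,E_uptake,0.4000000000000002
machine,translation,0.4000000000000002
target_concentration,housekeeping_protein,0.2
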