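record_id,dx_codes,px_codes,is_case,had_excision,had_hemorrhage
op-001,434.91;431,01.25,true,false,true
op-002,43311,0124;0153,true,true,false
op-003,434.11;852.21,01.25,false,,
op-004,433.01,01.25,false,,
op-005,434.91,01.25;03.09,false,,
op-006,722.10,80.51,false,,
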