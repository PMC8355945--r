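species,body_length_m,rate_commute_hz,rate_capture_hz,speed_commute_ms,speed_capture_ms
tagged_bat,0.077,7,150,7,2
sperm_whale,16,2,50,2,4
harbor_porpoise,1.5,25,300,1,2
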