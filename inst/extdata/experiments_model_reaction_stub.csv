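borane_id,yield_fraction,loading_fraction,time_h
B1a,0.50,0.05,6
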