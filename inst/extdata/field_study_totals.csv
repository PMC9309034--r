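stratum,total_mortality,n_collared
fawn,0.16,232
adult,0.03,545
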