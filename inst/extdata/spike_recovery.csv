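# chromocal spike-recovery series: Cr(VI) spiked into ultrapure water
spiked_ppb,recovery_pct
50,101.056
100,100.026
250,100.0324
500,99.9716
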