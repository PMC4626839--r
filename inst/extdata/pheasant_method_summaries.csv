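structure,method,measure,sex,mean,sd
brain,mr_manual,volume,female,3335,84
brain,mr_manual,volume,male,3752,154
brain,fakir_mr,volume,female,3383,131
brain,fakir_mr,volume,male,3729,197
brain,fakir_mr,surface,female,1394,39
brain,fakir_mr,surface,male,1538,80
endocranium,mr_manual,volume,female,4003,103
endocranium,mr_manual,volume,male,4344,160
endocranium,watershed_ct,volume,female,3642,52
endocranium,watershed_ct,volume,male,4036,172
endocranium,watershed_ct,surface,female,1500,37
endocranium,watershed_ct,surface,male,1572,91
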