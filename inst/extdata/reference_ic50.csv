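compound_id,carm1_ic50_nM,hdac2_ic50_nM,du145_inhibition_pct_1uM
CH-1,3.71,4.07,97
CH-2,5.38,8.33,93
CH-3,10.55,5.83,96
CH-4,25.54,9.18,92
CH-5,30.14,17.27,85
CH-6,37.37,12.96,86
CH-7,58.48,24.76,81
EZM2302,5.97,NA,NA
vorinostat,NA,9.53,89
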