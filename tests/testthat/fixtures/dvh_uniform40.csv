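# structure: PTV_Whole
# total_volume_cc: 164
# dose_unit: Gy
dose,volume_fraction
0,1
10,1
20,1
30,1
40,1
40.05,0
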