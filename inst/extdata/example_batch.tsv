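# biomass_gVSS_L: 0.9
# biomass_sd: 0.2
# units: time_h h; conc_mM mmol/L (nitrite)
# note: synthetic example of a nitrite depletion batch assay, two bottles
time_h	conc_mM	replicate
0	1.10	1
0.5	1.01	1
1	0.88	1
1.5	0.80	1
2	0.69	1
0	1.08	2
0.5	0.99	2
1	0.91	2
1.5	0.78	2
2	0.71	2
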