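gamma	median_spearman
0.3	-0.2285
0.35	-0.2928
0.4	-0.3604
0.45	-0.3952
0.5	-0.4553
0.55	-0.487
0.6	-0.5322
0.65	-0.5722
0.7	-0.6011
0.75	-0.6333
0.8	-0.6626
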