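sample_id	total_biovolume	total_biovolume_se
S1	1.28e9	0.06e9
S2	4.49e9	0.51e9
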