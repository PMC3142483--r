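# library domain=archaea clones_obtained=56 clones_sequenced=50
# library domain=bacteria clones_obtained=110 clones_sequenced=100
domain	group	count
archaea	ANME-2a	44
archaea	MBG-D	6
bacteria	Gammaproteobacteria	43
bacteria	Deltaproteobacteria (other)	9
bacteria	SEEP-SRB1a	8
bacteria	Other bacteria	40
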