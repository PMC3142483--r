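sample_id	group	category	mean	se	below_detection
S1	ANME-1	cells	NA	NA	TRUE
S1	ANME-1	aggregates	NA	NA	TRUE
S1	ANME-1	biovolume	NA	NA	TRUE
S1	ANME-2	cells	0.082	0.030	FALSE
S1	ANME-2	aggregates	0.371	0.062	FALSE
S1	ANME-2	biovolume	0.134	0.042	FALSE
S1	ANME-3	cells	0.001	0.001	FALSE
S1	ANME-3	aggregates	0.021	0.014	FALSE
S1	ANME-3	biovolume	0.015	0.015	FALSE
S1	SRB	cells	0.029	0.015	FALSE
S1	SRB	aggregates	0.320	0.062	FALSE
S1	SRB	biovolume	0.227	0.053	FALSE
S2	ANME-1	cells	NA	NA	TRUE
S2	ANME-1	aggregates	NA	NA	TRUE
S2	ANME-1	biovolume	NA	NA	TRUE
S2	ANME-2	cells	0.025	0.020	FALSE
S2	ANME-2	aggregates	0.472	0.082	FALSE
S2	ANME-2	biovolume	0.504	0.159	FALSE
S2	ANME-3	cells	0.001	0.001	FALSE
S2	ANME-3	aggregates	0.008	0.007	FALSE
S2	ANME-3	biovolume	0.024	0.018	FALSE
S2	SRB	cells	0.008	0.004	FALSE
S2	SRB	aggregates	0.376	0.050	FALSE
S2	SRB	biovolume	0.606	0.055	FALSE
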