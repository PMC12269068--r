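# illustrative goethite proton + NOM + steric tableau (singly coordinated sites only); FeNOMH logK is NOM-specific (here 6.0)
[components]
name	kind	charge	site_density
FeOH	surface_site	-0.5	3.45
HNOM	surface_component	-1	NA
S0	surface_component	0	NA
H	aqueous_master	1	NA
[species]
name	FeOH	HNOM	S0	H	dz0	dz1	dz2	logK
FeOH	1	0	0	0	0	0	0	0
FeOH2	1	0	0	1	1.0	0.0	0.0	9.3
FeNOM	1	1	0	0	 1.5	-1.0	-0.5	 0.0
FeNOMH	1	1	0	1	 1.5	-0.5	 0.0	 6.0
FeOH2NOM	1	1	0	0	 2.0	-1.5	-0.5	 0.6
S_FeOH	1	0	1	0	0	0	0	0
S_FeOH2	1	0	1	1	1.0	0.0	0.0	9.3
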