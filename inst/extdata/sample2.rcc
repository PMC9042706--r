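<Header>
FileVersion	1.7
SoftwareVersion	4.0.0.3
</Header>
<Sample_Attributes>
ID	SAMPLE_B
Owner	lab
Date	20210102
GeneRLF	SBCLN_panel
</Sample_Attributes>
<Lane_Attributes>
ID	2
FovCount	555
FovCounted	548
BindingDensity	0.58
</Lane_Attributes>
<Code_Summary>
CodeClass	Name	Accession	Count
Endogenous	BTLA	NM_181780.3	96
Endogenous	SOX11	NM_003108.3	501
Endogenous	BCL2	NM_000633.2	220
Housekeeping	ACTB	NM_001101.3	1802
Housekeeping	GAPDH	NM_002046.3	1410
Positive	POS_A(128)	ERCC_00117.1	2890
Negative	NEG_A(0)	ERCC_00096.1	2
</Code_Summary>
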