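<Header>
FileVersion,1.7
SoftwareVersion,4.0.0.3
</Header>
<Sample_Attributes>
ID,SAMPLE_A
Owner,lab
Comments,
Date,20210101
GeneRLF,SBCLN_panel
SystemAPF,n6_vDV1
</Sample_Attributes>
<Lane_Attributes>
ID,1
FovCount,555
FovCounted,550
BindingDensity,0.62
</Lane_Attributes>
<Code_Summary>
CodeClass,Name,Accession,Count
Endogenous,BTLA,NM_181780.3,412
Endogenous,SOX11,NM_003108.3,37
Endogenous,BCL2,NM_000633.2,880
Housekeeping,ACTB,NM_001101.3,2514
Housekeeping,GAPDH,NM_002046.3,1933
Positive,POS_A(128),ERCC_00117.1,3120
Negative,NEG_A(0),ERCC_00096.1,4
</Code_Summary>
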