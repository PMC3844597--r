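drug	mechanism	Ki_nM
MIA	NET	316.2
MIA	HTR2A	316.2
MIA	HTR2C	316.2
MIA	HRH1	10
MIA	ADRA1A	316.2
MIA	CHRM	316.2
IMI	SERT	10
IMI	NET	316.2
IMI	HTR2C	316.2
IMI	HRH1	316.2
IMI	ADRA1A	316.2
IMI	CHRM	316.2
FLU	SERT	10
FLU	NET	316.2
FLU	HTR2C	316.2
BUP	DAT	10
TRA	MAO	10
MET	NET	10
MET	DAT	10
COC	SERT	316.2
COC	NET	316.2
COC	DAT	10
MOR	OPRM1	10
ETO	GABAA	10
DIA	GABAA	10
BUS	HTR1A	10
CLO	HTR2A	316.2
CLO	HTR2C	316.2
CLO	HRH1	316.2
CLO	ADRA1A	316.2
CLO	CHRM	316.2
CLO	DRD2	10
RIS	HTR2A	10
RIS	HTR2C	316.2
RIS	HRH1	316.2
RIS	ADRA1A	316.2
RIS	DRD2	10
HAL	HTR2A	316.2
HAL	DRD2	10
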