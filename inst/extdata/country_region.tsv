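country	region
DE	Europe
FR	Europe
GB	Europe
IT	Europe
ES	Europe
NL	Europe
SE	Europe
CH	Europe
PL	Europe
BE	Europe
US	NorthAmerica
CA	NorthAmerica
MX	NorthAmerica
JP	Asia
CN	Asia
IN	Asia
KR	Asia
TW	Asia
SG	Asia
AU	Oceania
NZ	Oceania
BR	SouthAmerica
AR	SouthAmerica
CL	SouthAmerica
CO	SouthAmerica
ZA	Africa
NG	Africa
EG	Africa
KE	Africa
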