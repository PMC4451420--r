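abb	name	tax	dataset	n	ho	fis
ABO	Abondance	Bos taurus	2	22	0.308	0.089
ANG	Angus	Bos taurus	1	61	0.305	0.098
AUB	Aubrac	Bos taurus	2	22	0.301	0.112
BPN	Bretonne black pied	Bos taurus	2	18	0.317	0.064
BRU	French brown swiss	Bos taurus	2	18	0.288	0.15
BSW	Brown swiss	Bos taurus	1	24	0.28	0.171
CHA	Charolais	Bos taurus	1	20	0.314	0.071
CHL	Charolais	Bos taurus	2	26	0.32	0.054
GAS	Gascon	Bos taurus	2	22	0.305	0.1
GNS	Guernsey	Bos taurus	1	21	0.275	0.188
HFD	Hereford	Bos taurus	1	31	0.304	0.101
HO2	Holstein	Bos taurus	2	31	0.316	0.066
HOf	Holstein	Bos taurus	1	30	0.313	0.077
HOL	Holstein	Bos taurus	2	64	0.319	0.057
JE2	Jersey	Bos taurus	2	28	0.263	0.223
JEf	Jersey	Bos taurus	1	21	0.277	0.18
JER	Jersey	Bos taurus	2	28	0.263	0.223
LMS	Limousin	Bos taurus	1	44	0.309	0.086
MAN	Maine-Anjou (Rouge des Près)	Bos taurus	2	16	0.303	0.105
MAR	Maraichine (Parthenaise)	Bos taurus	2	19	0.318	0.059
MON	Montbeliarde	Bos taurus	2	30	0.299	0.116
NOR	Normande	Bos taurus	2	30	0.307	0.094
NRC	Norwegian red cattle	Bos taurus	1	21	0.317	0.063
OUL	Oulmès Zaer	Bos taurus	2	27	0.288	0.149
PMT	Piedmontese	Bos taurus	1	24	0.321	0.053
PRP	French red pied lowland	Bos taurus	2	22	0.325	0.039
RGU	Red Angus	Bos taurus	1	15	0.305	0.1
RMG	Romagnola	Bos taurus	1	24	0.291	0.141
ROM	Romagnola	Bos taurus	3	13	0.293	0.134
CHI	Chianina	Bos taurus	3	14	0.285	0.158
CIL	Chillingham	Bos taurus	3	16	0.026	0.924
W_P	White park	Bos taurus	3	15	0.245	0.276
SAL	Salers	Bos taurus	2	22	0.285	0.157
TAR	Tarine	Bos taurus	2	18	0.3	0.113
VOS	Vosgienne	Bos taurus	2	20	0.312	0.078
BAO	Baoule	Bos taurus	2	29	0.216	0.362
LAG	Lagune	Bos taurus	2	30	0.183	0.46
NDA	N'Dama	Bos taurus	1	25	0.209	0.381
ND1	N'Dama	Bos taurus	2	14	0.235	0.307
ND2	N'Dama	Bos taurus	2	17	0.237	0.299
ND3	N'Dama	Bos taurus	2	25	0.21	0.381
SOM	Somba	Bos taurus	2	30	0.217	0.359
BRM	Brahman	Bos indicus	1	25	0.19	0.44
GIR	Gir	Bos indicus	1	24	0.16	0.528
NEL	Nelore	Bos indicus	1	21	0.161	0.524
ZBO	Zebu Bororo	Bos indicus	2	23	0.24	0.292
ZFU	Zebu Fulani	Bos indicus	2	30	0.241	0.289
ZMA	Zebu from Madagascar	Bos indicus	2	30	0.194	0.427
BMA	Beefmaster	hybrid	1	24	0.328	0.031
SGT	Santa Gertrudis	hybrid	1	24	0.313	0.075
BOR	Borgou	hybrid	2	30	0.263	0.222
KUR	Kuri	hybrid	2	30	0.261	0.229
SHK	Sheko	hybrid	1	20	0.25	0.26
SIM	Simmental	Bos taurus	1	3	NA	NA
GBV	Gelbvieh	Bos taurus	1	3	NA	NA
OBB	North American Bison	Bos Bison	2	4	NA	NA
OBJ	Banteng	Bos javanicus	1	2	NA	NA
OGR	Gaur	Bos gaurus	1	4	NA	NA
OYK	Yak	Bos grunniens	1	2	NA	NA
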