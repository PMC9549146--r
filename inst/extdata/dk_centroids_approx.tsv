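structure	hemisphere	x	y	z
AMYGDALA	LH	-24	-4	-18
AMYGDALA	RH	24	-4	-18
BANKSSTS	LH	-52	-46	8
BANKSSTS	RH	52	-46	8
CAUDALANTERIORCINGULATE	LH	-6	22	26
CAUDALANTERIORCINGULATE	RH	6	22	26
CAUDALMIDDLEFRONTAL	LH	-38	12	46
CAUDALMIDDLEFRONTAL	RH	38	12	46
ENTORHINAL	LH	-26	-8	-32
ENTORHINAL	RH	26	-8	-32
FUSIFORM	LH	-36	-52	-18
FUSIFORM	RH	36	-52	-18
HIPPOCAMPUS	LH	-28	-24	-12
HIPPOCAMPUS	RH	28	-24	-12
INFERIORPARIETAL	LH	-44	-62	36
INFERIORPARIETAL	RH	44	-62	36
INFERIORTEMPORAL	LH	-52	-44	-22
INFERIORTEMPORAL	RH	52	-44	-22
INSULA	LH	-36	0	2
INSULA	RH	36	0	2
ISTHMUSCINGULATE	LH	-8	-46	26
ISTHMUSCINGULATE	RH	8	-46	26
LATERALOCCIPITAL	LH	-38	-82	2
LATERALOCCIPITAL	RH	38	-82	2
LATERALORBITOFRONTAL	LH	-26	32	-14
LATERALORBITOFRONTAL	RH	26	32	-14
LINGUAL	LH	-14	-70	-4
LINGUAL	RH	14	-70	-4
MEDIALORBITOFRONTAL	LH	-8	40	-16
MEDIALORBITOFRONTAL	RH	8	40	-16
MIDDLETEMPORAL	LH	-56	-30	-10
MIDDLETEMPORAL	RH	56	-30	-10
PARACENTRAL	LH	-8	-26	58
PARACENTRAL	RH	8	-26	58
PARAHIPPOCAMPAL	LH	-26	-32	-16
PARAHIPPOCAMPAL	RH	26	-32	-16
PARSOPERCULARIS	LH	-50	14	14
PARSOPERCULARIS	RH	50	14	14
PARSORBITALIS	LH	-44	38	-10
PARSORBITALIS	RH	44	38	-10
PARSTRIANGULARIS	LH	-46	30	6
PARSTRIANGULARIS	RH	46	30	6
POSTCENTRAL	LH	-42	-26	50
POSTCENTRAL	RH	42	-26	50
POSTERIORCINGULATE	LH	-6	-36	38
POSTERIORCINGULATE	RH	6	-36	38
PRECENTRAL	LH	-40	-12	48
PRECENTRAL	RH	40	-12	48
PRECUNEUS	LH	-10	-58	38
PRECUNEUS	RH	10	-58	38
ROSTRALANTERIORCINGULATE	LH	-6	38	8
ROSTRALANTERIORCINGULATE	RH	6	38	8
ROSTRALMIDDLEFRONTAL	LH	-34	44	20
ROSTRALMIDDLEFRONTAL	RH	34	44	20
SUPERIORFRONTAL	LH	-12	26	52
SUPERIORFRONTAL	RH	12	26	52
SUPERIORPARIETAL	LH	-24	-60	54
SUPERIORPARIETAL	RH	24	-60	54
SUPERIORTEMPORAL	LH	-54	-16	0
SUPERIORTEMPORAL	RH	54	-16	0
SUPRAMARGINAL	LH	-54	-40	32
SUPRAMARGINAL	RH	54	-40	32
TEMPORALPOLE	LH	-34	14	-32
TEMPORALPOLE	RH	34	14	-32
TRANSVERSETEMPORAL	LH	-46	-22	10
TRANSVERSETEMPORAL	RH	46	-22	10
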