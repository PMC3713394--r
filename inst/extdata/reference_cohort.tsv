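# Per-participant stochastic signatures of the 15 analysable members of the
# published smartphone-accelerometry cohort (6 normal controls, 9 Parkinson's
# patients), transcribed from the study's printed results table: Gamma
# (shape, scale) estimates of each person's speed-peak distribution with 95%
# confidence bounds, age, and the min/max shift of the speed profile.
# The Fano factor of each signature equals its scale.
participant	label	age	shape	scale	shapeLo	shapeHi	scaleLo	scaleHi	minShift	maxShift
Daisy	PD	54	2.1892	1.6624	1.929	2.483	1.442	1.915	1.0147	22.8752
Cherry	PD	55	2.8527	0.7797	1.893	4.298	0.498	1.220	1.0252	6.5693
Orchid	PD	69	0.7476	13.4048	0.643	0.869	0.886	14.51	1.0079	83.6943
Crocus	PD	46	1.3966	4.6465	1.199	1.626	3.870	5.578	1.0012	36.2181
Maple	PD	55	0.8482	8.5078	0.742	0.969	7.114	9.18	1.0032	52.6980
Flox	PD	57	0.9854	6.6008	0.823	1.181	5.231	7.329	1.0207	44.3045
Violet	PD	55	0.8260	6.0915	0.675	1.011	4.643	7.993	1.0043	35.8459
Peony	PD	80	1.0905	3.9342	0.885	1.343	3.026	5.114	1.0014	27.7137
Iris	PD	65	1.0631	6.8824	0.684	1.651	3.941	9.02	1.1204	36.5351
Dafo	NC	42	1.3953	3.1758	1.185	1.642	2.612	3.861	1.0153	29.0774
Rose	NC	55	2.1209	1.9402	1.443	3.117	1.257	2.995	1.0033	17.0063
Orange	NC	57	2.9601	0.9281	2.318	3.779	0.711	1.211	1.0126	12.2356
Sunf	NC	67	3.2197	0.6442	2.109	4.914	0.407	1.018	1.0005	6.5434
Apple	NC	77	3.8684	0.5716	2.795	5.354	0.404	0.808	1.0185	7.4658
Sweetp	NC	77	3.5192	0.6395	2.203	5.623	0.386	1.058	1.0014	6.8278
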