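clade	n	t	t_lo	t_hi
Centropogonids	556	5.02	3.95	6.13
Espeletiinae	120	4.04	2.42	5.92
Lupinus_Andean	81	1.47	1.18	1.76
Hawaiian_lobeliads	126	13.6	10.49	16.71
Silversword_alliance	28	5.2	4.4	6.0
Hummingbirds_all	338	22.4	20.3	24.7
Bee_hummingbirds	36	5	NA	NA
Dianthus	200	1.5	0.9	2.1
African_cichlids	1800	2.4	1.22	4.02
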