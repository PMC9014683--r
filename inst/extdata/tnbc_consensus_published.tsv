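sample_id	rank_sprm	rank_rskc	rank_enetlts	rp	p	q
TCGA-E9-A22G	1	94	1	94	0	0.0014
TCGA-A2-A0YJ	2	90	8	1440	0	0.0230
TCGA-A2-A4S1	61	1	43	2623	0.0001	0.0243
TCGA-A7-A13E	9	154	2	2772	0.0001	0.0243
TCGA-A2-A04U	5	168	4	3360	0.0001	0.0243
TCGA-LL-A6FR	13	79	5	5135	0.0002	0.0296
TCGA-AR-A0TP	10	91	6	5460	0.0002	0.0296
TCGA-AR-A251	3	296	7	6216	0.0002	0.0299
TCGA-AN-A0FJ	6	78	22	10296	0.0004	0.0410
TCGA-OL-A5S0	8	402	3	9648	0.0004	0.0410
TCGA-AN-A0FL	39	13	24	12168	0.0005	0.0444
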