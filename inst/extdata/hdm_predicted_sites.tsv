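site_id	target	protein_id	proteases	window	p1_index	ecd_start	ecd_end
DC-SIGN	DC-SIGN	Q9NNX6	Der p 1	LVVIKSAEE	295	59	404
IL-1RII	IL-1RII	P27930	Der p 1	PVALRCPQV	49	14	343
IL-12RBII	IL-12RBII	Q99665	Der p 1	AVAVSAANS	398	24	622
IL-17RB	IL-17RB	Q9NRM6	Der p 1	KKCVKAGSL	175	18	292
IL-23R_site2	IL-23R	Q5VWK5	Der p 1	VVHVKSLET	163	24	355
CLEC1A	CLEC1A	Q8NC01	Der p 1	VQNIKLAGS	109	74	280
CD163b	CD163b	Q9NR16	Der p 1	RVEVKHADT	811	41	1359
IL-3RA	IL-3RA	P26951	Der p 1;Der p 3	LVRGRSAAF	187	19	305
IL-4R	IL-4R	P24394	Der p 1;Der p 3	HVKPRAPGN	124	26	232
IL-10RA	IL-10RA	Q13651	Der p 1;Der p 3	GYRARVRAV	99	22	235
IL-18R1	IL-18R1	Q13478	Der p 1;Der p 3	ILVRKADMA	315	22	319
EphRB1	EphRB1	P54762	Der p 1;Der p 3	VVQVRARTV	507	18	540
IL-23R_site1	IL-23R	Q5VWK5	Der p 1;Der p 6	LVWVQAANA	197	24	355
CD23	CD23	P06734	Der p 3	QLEERAARN	59	48	321
IL-23R_site3	IL-23R	Q5VWK5	Der p 3	AVISRAETI	227	24	355
MMR1	MMR1	P22897	Der p 3	PGGRRSSLS	1042	19	1389
SSTR4	SSTR4	P31391	Der p 3	PGDARAAGM	43	1	46
IL-5RAII	IL-5RAII	Q01344	Der p 6	LHKGFSASV	94	21	342
IL-17RCII	IL-17RCII	Q8NAC3	Der p 6	VVLSFQAYP	200	21	538
IL-17RE_site1	IL-17RE	Q8NRF9	Der p 6	SFTGSSAYI	51	24	454
IL-17RE_site2	IL-17RE	Q8NRF9	Der p 6	MHATFSAAW	386	24	454
CD1b	CD1b	P29016	Der p 6	RAQKFCALI	162	18	303
CD109	CD109	Q6YHK3	Der p 6	EDGSFSAFG	974	22	1420
MST1R	MST1R	Q04912	Der p 6	VVPSFSAGG	49	25	297
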