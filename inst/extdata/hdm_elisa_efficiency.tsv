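site_id	protease	window	mean_da_over_a	sem	predicted
IL-12RBII	Der p 1	AVAVSAANS	90.9	1.4	yes
SSTR4	Der p 1	PGDARAAGM	73.4	1.1	no
IL-1RII	Der p 1	PVALRCPQV	65.0	1.8	yes
IL-23R_site2	Der p 1	VVHVKSLET	62.8	12.7	yes
EphRB1	Der p 1	VVQVRARTV	61.1	6.7	yes
IL-23R_site1	Der p 1	LVWVQAANA	43.1	2.2	yes
MMR1	Der p 1	PGGRRSSLS	31.6	1.3	no
IL-3RA	Der p 1	LVRGRSAAF	21.5	15.5	yes
IL-10RA	Der p 1	GYRARVRAV	17.9	11.3	yes
CLEC1A	Der p 1	VQNIKLAGS	6.1	2.12	yes
IL-4R	Der p 1	HVKPRAPGN	5.5	0.5	yes
IL-17RB	Der p 1	KKCVKAGSL	5.2	2.5	yes
IL-18R1	Der p 1	ILVRKADMA	4.9	4.52	yes
DC-SIGN	Der p 1	LVVIKSAEE	4.2	1.9	yes
IL-23R_site3	Der p 1	AVISRAETI	3.8	0.3	no
ctrl_neg	Der p 1	GGSGGSGGS	1.15	0.1	no
IL-3RA	Der p 3	LVRGRSAAF	83.8	0.2	yes
IL-18R1	Der p 3	ILVRKADMA	70.0	9	yes
EphRB1	Der p 3	VVQVRARTV	67.2	1.7	yes
IL-10RA	Der p 3	GYRARVRAV	54.0	8.0	yes
ctrl_neg	Der p 3	GGSGGSGGS	3.0	0.6	no
CD109	Der p 6	EDGSFSAFG	94.1	0.1	yes
IL-17RE_site2	Der p 6	MHATFSAAW	87.9	0.1	yes
IL-17RE_site1	Der p 6	SFTGSSAYI	84.1	1.2	yes
IL-23R_site1	Der p 6	LVWVQAANA	69.4	2.3	yes
CD1b	Der p 6	RAQKFCALI	30.4	2.0	yes
IL-12RBII	Der p 6	AVAVSAANS	4.7	0.6	no
MST1R	Der p 6	VVPSFSAGG	4.3	2.1	yes
IL-1RII	Der p 6	PVALRCPQV	2.9	1.1	no
IL-5RAII	Der p 6	LHKGFSASV	2.5	0.8	yes
IL-17RCII	Der p 6	VVLSFQAYP	2.4	0.2	yes
IL-23R_site3	Der p 6	AVISRAETI	1.9	0.4	no
ctrl_neg	Der p 6	GGSGGSGGS	0.0	0.0	no
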