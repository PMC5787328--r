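line	model	b	sigma2_a	sigma2_d	sigma2_r	sigma2_c	lambda	sigma2_e	I_D	V_A	V_D	h2	d2	LogCPO	DIC
1	SN	NA	0.0000394	0.0000369	0.160	0.478	NA	6.569	-0.016	0.679	0.597	0.080	0.070	-32508.88	64939.52
1	AN	NA	0.0000345	0.0000769	0.161	0.308	0.000380	6.570	-0.044	0.862	1.326	0.093	0.143	-32513.61	64948.21
1	SC	-12.153	0.0000439	0.0000122	0.160	0.572	NA	6.567	-0.045	0.832	0.415	0.097	0.048	-32498.72	64920.97
1	Full	-7.950	0.0000381	0.0000536	0.161	0.394	0.000135	6.568	-0.045	0.859	1.013	0.095	0.111	-32517.83	64947.08
2	SN	NA	0.0000678	0.0000430	0.299	0.580	NA	6.630	-0.008	1.100	0.669	0.119	0.072	-28176.11	56250.06
2	AN	NA	0.0000617	0.0000872	0.296	0.380	0.000249	6.635	-0.028	1.170	1.377	0.118	0.139	-28176.62	56251.39
2	SC	-6.479	0.0000701	0.0000334	0.299	0.614	NA	6.631	-0.025	1.152	0.574	0.124	0.061	-28174.84	56247.95
2	Full	1.726	0.0000615	0.0000993	0.297	0.333	0.000307	6.635	-0.029	1.198	1.537	0.120	0.152	-28180.68	56258.66
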