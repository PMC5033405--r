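sample_id	status	sex	age	HLA-C*06	rs26653	LCE3C_LCE3B-del	rs17589	rs17695937
S0001	1	0	23	0	0	0	0	0
S0002	1	1	53	1	2	0	2	0
S0003	1	0	49	1	0	0	1	1
S0004	1	1	64	1	0	1	0	1
S0005	1	0	21	1	1	1	0	1
S0006	1	0	33	2	1	1	1	1
S0007	1	0	64	1	0	0	0	NA
S0008	1	1	26	0	0	0	1	1
S0009	1	1	65	0	2	1	1	0
S0010	1	1	31	NA	1	1	0	1
S0011	1	0	94	0	1	1	0	1
S0012	1	1	37	1	1	0	0	0
S0013	1	1	30	1	2	1	1	0
S0014	1	0	43	0	1	1	2	1
S0015	1	1	41	1	1	0	1	0
S0016	1	1	56	0	1	0	0	NA
S0017	0	0	40	0	0	1	0	1
S0018	0	0	41	0	1	0	1	0
S0019	0	0	56	0	1	0	1	2
S0020	0	0	31	0	0	0	1	1
S0021	0	0	65	1	1	2	NA	1
S0022	0	0	43	0	0	1	0	2
S0023	0	0	42	0	1	1	0	1
S0024	0	0	67	0	1	1	0	0
S0025	0	1	51	0	NA	0	1	1
S0026	0	1	65	0	0	1	0	1
S0027	0	1	30	0	0	0	1	2
S0028	0	1	44	0	0	0	2	1
S0029	0	1	55	0	0	1	1	NA
S0030	0	1	47	0	NA	0	1	NA
S0031	0	0	39	0	1	0	0	0
S0032	0	0	32	0	1	1	1	1
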