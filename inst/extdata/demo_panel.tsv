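name	risk_allele	marker_class
HLA-C*06	HLA-C*06	HLA-presence
rs26653	G	SNP
LCE3C_LCE3B-del	del	deletion
rs17589	T	SNP
rs17695937	A	SNP
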