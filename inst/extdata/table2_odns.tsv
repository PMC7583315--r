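gene_id	rsid	rsid_alt	id_conflict	allele_class	allele_label	offset	sequence	snp_position	predicted_neglog_kd	measured_kd_nM	measured_sem_nM
SHOX	rs1452787381	NA	FALSE	WT	-45A	-45	GAGGTCGCCGCGTATAAATAGTGAGA	14	20.31	39	7
SHOX	rs1452787381	NA	FALSE	min	-45G	-45	GAGGTCGCCGCGTGTAAATAGTGAGA	14	19.21	260	70
GTPBP6	rs1393008234	NA	FALSE	WT	-24G	-24	ATCACGAGCACGTGATGAGGAGCGGC	14	17.3	1500	200
GTPBP6	rs1393008234	NA	FALSE	min	-24T	-24	ATCACGAGCACGTTATGAGGAGCGGC	14	18.68	1400	200
ASMT	rs1402972626	NA	FALSE	WT	-30G	-30	GGTGACCTTTTGTGCCCAGAATAGGT	14	18.18	600	300
ASMT	rs1402972626	NA	FALSE	min	-30A	-30	GGTGACCTTTTGTACCCAGAATAGGT	14	18.93	1000	300
ZFY	rs1452787381	rs1388535808;rs996955491	TRUE	WT	-56C	-56	GGCGGAGGGGGCCCAACTACCATCCC	14	17.67	1000	400
ZFY	rs1452787381	rs1388535808;rs996955491	TRUE	min	-56T	-56	GGCGGAGGGGGCCTAACTACCATCCC	14	18.18	2000	1000
CDY2A	rs20067072	rs200670724	TRUE	WT	-24G	-24	AGAATGTTCCATATAATCGTCATAGC	14	19.27	160	30
CDY2A	rs20067072	rs200670724	TRUE	min	-24t	-24	AGAATGTTCCATACAATCGTCATAGC	14	18.76	500	200
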