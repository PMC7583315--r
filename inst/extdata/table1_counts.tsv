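class_label	context	n_gene	n_snp	n_res	n_gt	n_lt	n_up	n_dn	note
genome_norm_tf_sites	TRUE	10000	100000	1000	200	800	NA	NA	NA
clinical_tbp_markers	TRUE	33	203	51	14	37	NA	NA	NA
female_reproductive_potential	TRUE	22	129	24	19	5	NA	NA	NA
PAR1	FALSE	15	899	211	143	68	101	110	affinity split tabulated as 143/68; running text says 146/68
PAR2	FALSE	3	135	25	20	5	10	15	NA
paralogous	FALSE	8	56	13	8	5	4	9	NA
unique	FALSE	6	41	12	6	6	4	8	NA
y_linked_subtotal	FALSE	32	1131	261	176	85	119	142	NA
TOTAL	FALSE	63	1206	261	176	85	119	142	NA
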