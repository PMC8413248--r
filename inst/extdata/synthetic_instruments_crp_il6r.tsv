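# Synthetic instrument table for the simulator's CRP- and IL6R-region SNPs.
# Betas are per-allele effects on log-CRP (mg/L); entirely simulated, not
# drawn from any published GWAS.
snp	effect_allele	other_allele	eaf	beta	se	n
g_CRP_1	A	G	0.32	0.199	0.004	204402
g_CRP_2	A	G	0.18	0.151	0.005	204402
g_CRP_3	A	G	0.41	0.118	0.004	204402
g_CRP_4	A	G	0.25	0.102	0.004	204402
g_IL6R_1	A	G	0.39	0.074	0.004	204402
g_IL6R_2	A	G	0.15	0.061	0.005	204402
g_IL6R_3	A	G	0.28	0.050	0.004	204402
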