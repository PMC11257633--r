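x_gene	xi_expressed	y_gene	survival_fraction_printed	branch_length_MY	stratum_max_MY
DDX3X	TRUE	DDX3Y	1.00	663	663
KDM6A	TRUE	UTY	1.00	663	663
ZFX	TRUE	ZFY	1.00	663	663
NLGN4X	TRUE	NLGN4Y	1.00	140	140
USP9X	TRUE	USP9Y	0.990	656	663
PRKX	TRUE	PRKY	0.851	74	NA
EIF1AX	TRUE	EIF1AY	0.833	552	663
KDM5C	TRUE	KDM5D	0.831	687	NA
TXLNG	TRUE	TXLNGY	0.664	440	663
RPS4X	TRUE	RPS4Y	0.355	343	967
SOX3	FALSE	SRY	1.000	967	967
RBMX	FALSE	RBMY	0.943	912	967
HSFX1	FALSE	HSFY1	0.834	806	967
TSPYL2	FALSE	TSPY	0.776	642	NA
AMELX	FALSE	AMELY	0.685	454	663
TBL1X	FALSE	TBL1Y	0.644	90	NA
TMSB4X	FALSE	TMSB4Y	0.465	308	663
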