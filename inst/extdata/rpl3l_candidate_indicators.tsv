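gene_id	mgi_id	chrom	pos_mb	mean_expression	coding_variant	cis_regulation	sig_corr	rgd_causal	functional
Myl4	17896	11	104.550663	10.8	Nonsyn	--	Y	Y	Y
Ace	11421	11	105.967945	11.7	--	Y	Y	--	Y
Kpna2	16647	11	106.988629	10.3	Nonsyn	Y	Y	--	--
Golm1	105348	13	59.640163	9.8	Nonsyn	Y	Y	--	--
Zfp367	238673	13	64.133022	8.3	Nonsyn	Y	Y	--	--
Zfp712	78251	13	67.038594	8.6	Nonsyn	Y	Y	--	--
Zfp759	268670	13	67.128226	8.7	Nonsyn	Y	Y	--	--
Zfp874a	238692	13	67.426259	8.2	Nonsyn	Y	Y	--	--
Zfp729a	212281	13	67.617001	10.5	Nonsyn	Y	Y	--	--
Mtrr	210009	13	68.56078	9.4	Nonsyn	Y	Y	--	--
Sdha	66945	13	74.322254	14.6	--	--	Y	Y	Y
Rhobtb3	73296	13	75.869537	10.0	Nonsyn	Y	Y	--	--
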