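response	date_label	link	alpha	beta_w	se_w	p_w	beta_p	se_p	p_p	beta_int	se_int	p_int	n_obs
barnacle_abundance	June	log	NA	-0.693	0.149	0.0000033	2.087	0.120	0	0.414	0.182	0.023	24
barnacle_abundance	season	log	NA	-0.887	0.214	0.0000339	2.087	0.210	0	0.507	0.299	0.090	168
grazer_occurrence	season	logit	NA	-1.640	1.225	0.181	2.865	0.768	0.000191	3.737	2.597	0.150	168
macroalgae_cover	season	logit	NA	-0.608	0.297	0.041	0.632	0.285	0.027	0.317	0.410	0.439	168
cyanobacteria_concentration	season	identity	NA	-0.011	0.009	0.188	0.268	0.026	0	0.086	0.039	0.030	168
diatom_concentration	season	identity	NA	-0.004	0.047	0.927	0.230	0.047	0.0000010	-0.003	0.066	0.963	168
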