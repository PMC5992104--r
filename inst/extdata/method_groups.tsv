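mi_term	group	is_apms
MI:0018	two hybrid	FALSE
MI:0397	two hybrid	FALSE
MI:0398	two hybrid	FALSE
MI:0399	two hybrid	FALSE
MI:1112	two hybrid	FALSE
MI:0006	coimmunoprecipitation	FALSE
MI:0007	coimmunoprecipitation	FALSE
MI:0019	coimmunoprecipitation	FALSE
MI:0096	pull down	FALSE
MI:0004	apms	TRUE
MI:0676	apms	TRUE
MI:0943	apms	TRUE
MI:0030	cross-linking	FALSE
MI:0031	cross-linking	FALSE
MI:0055	imaging	FALSE
MI:0416	imaging	FALSE
MI:0663	imaging	FALSE
MI:0415	enzymatic study	FALSE
MI:0424	enzymatic study	FALSE
MI:0089	protein array	FALSE
MI:0114	structure	FALSE
MI:0107	biophysical	FALSE
MI:0921	biophysical	FALSE
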