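mediator	outcome	beta1	se1	beta2	se2	beta0	se0
PUFA/MUFA ratio	T2DM	0.107	0.026	-0.819	0.246	-1.113	0.235
PUFA/TFA ratio	T2DM	0.095	0.025	-0.846	0.254	-1.113	0.235
Omega-6/TFA ratio	T2DM	0.106	0.028	-0.850	0.255	-1.113	0.235
LA/TFA ratio	T2DM	0.082	0.025	-0.807	0.261	-1.113	0.235
PUFA/MUFA ratio	Fasting glucose	0.107	0.026	-0.079	0.022	-0.061	0.015
PUFA/TFA ratio	Fasting glucose	0.095	0.025	-0.083	0.022	-0.061	0.015
Omega-6/TFA ratio	Fasting glucose	0.106	0.028	-0.081	0.022	-0.061	0.015
LA/TFA ratio	Fasting glucose	0.082	0.025	-0.078	0.022	-0.061	0.015
PUFA/MUFA ratio	Fasting insulin	0.107	0.026	-0.069	0.021	-0.080	0.014
PUFA/TFA ratio	Fasting insulin	0.095	0.025	-0.068	0.021	-0.080	0.014
Omega-6/TFA ratio	Fasting insulin	0.106	0.028	-0.074	0.021	-0.080	0.014
LA/TFA ratio	Fasting insulin	0.082	0.025	-0.074	0.021	-0.080	0.014
PUFA/MUFA ratio	Two-hour glucose	0.107	0.026	-0.304	0.063	-0.250	0.056
PUFA/TFA ratio	Two-hour glucose	0.095	0.025	-0.269	0.064	-0.250	0.056
Omega-6/TFA ratio	Two-hour glucose	0.106	0.028	-0.245	0.063	-0.250	0.056
LA/TFA ratio	Two-hour glucose	0.082	0.025	-0.239	0.062	-0.250	0.056
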