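TASK_ID	DESCRIPTION	CATEGORY	SHOULD_FAIL	IN	IN_LB	IN_UB	OUT	OUT_LB	OUT_UB	EQU
GROWTH	biomass growth from minimal medium	growth	FALSE	glc[s]	0	10	biomass[c]		1000	
				nh3[s]	0	1000	co2[s]	0	1000	
				pi[s]	0	1000	h2o[s]	0	1000	
				o2[s]	0	1000	lac[s]	0	1000	
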