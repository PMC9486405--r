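site_group	node	subtype_group	variable	level	count
oral_cavity	N0	mesenchymal	total	all	26
oral_cavity	N0	non_mesenchymal	total	all	93
oral_cavity	N+	mesenchymal	total	all	53
oral_cavity	N+	non_mesenchymal	total	all	97
non_oral_cavity	N0	mesenchymal	total	all	10
non_oral_cavity	N0	non_mesenchymal	total	all	46
non_oral_cavity	N+	mesenchymal	total	all	20
non_oral_cavity	N+	non_mesenchymal	total	all	73
oral_cavity	N0	mesenchymal	T_stage	T1	3
oral_cavity	N0	mesenchymal	T_stage	T2	15
oral_cavity	N0	mesenchymal	T_stage	T3	3
oral_cavity	N0	mesenchymal	T_stage	T4	5
oral_cavity	N+	mesenchymal	T_stage	T1	3
oral_cavity	N+	mesenchymal	T_stage	T2	14
oral_cavity	N+	mesenchymal	T_stage	T3	14
oral_cavity	N+	mesenchymal	T_stage	T4	22
oral_cavity	N0	non_mesenchymal	T_stage	T1	16
oral_cavity	N0	non_mesenchymal	T_stage	T2	24
oral_cavity	N0	non_mesenchymal	T_stage	T3	18
oral_cavity	N0	non_mesenchymal	T_stage	T4	35
oral_cavity	N+	non_mesenchymal	T_stage	T1	5
oral_cavity	N+	non_mesenchymal	T_stage	T2	26
oral_cavity	N+	non_mesenchymal	T_stage	T3	23
oral_cavity	N+	non_mesenchymal	T_stage	T4	43
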