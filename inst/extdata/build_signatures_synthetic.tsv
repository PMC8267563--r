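rsid	chrom	pos_grch36	pos_grch37	pos_grch38
rs99001	18	12160922	12162094	12169493
rs99002	2	15081466	15086377	15090152
rs99003	14	39455820	39459215	39465413
rs99004	8	31721962	31725405	31729560
rs99005	22	23058646	23061473	23065823
rs99006	3	9630276	9634015	9639277
rs99007	21	18530737	18535423	18538238
rs99008	22	35696029	35700850	35705490
rs99009	22	39753658	39756863	39764375
rs99010	21	36650214	36651843	36661513
rs99011	3	3908169	3910518	3914369
rs99012	14	18464579	18467988	18474617
rs99013	9	11133203	11137742	11144633
rs99014	4	20919507	20920260	20926835
rs99015	1	7990221	7992038	7999215
rs99016	13	29946687	29948103	29956621
rs99017	21	5732512	5736825	5740762
rs99018	22	12998944	13002127	13007174
rs99019	15	20786464	20788714	20795111
rs99020	8	20767972	20771908	20778516
rs99021	1	25668395	25669306	25674783
rs99022	18	23733959	23735915	23740466
rs99023	12	38635377	38636689	38643296
rs99024	14	24526461	24530377	24538030
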