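chrom	pos	allele_a	allele_b	gene
1	31537813	T	G	REVGENE06
2	7949828	A	G	REVGENE09
2	15781075	A	G	REVGENE04
2	26921565	T	G	REVGENE03
3	21255392	A	G	REVGENE07
3	28016409	A	G	REVGENE04
4	28326798	A	G	REVGENE07
4	34363779	T	C	REVGENE02
5	17461120	T	C	REVGENE09
5	22113832	T	C	REVGENE09
5	39216902	T	G	REVGENE04
5	43997063	T	C	REVGENE06
6	17407826	A	C	REVGENE01
6	19703976	T	G	REVGENE07
6	44960719	T	G	REVGENE05
7	9179020	A	C	REVGENE07
7	28088956	T	C	REVGENE05
7	42483887	T	G	REVGENE02
8	29638331	T	G	REVGENE12
9	24311372	T	G	REVGENE07
10	21266731	T	G	REVGENE05
10	32692668	T	C	REVGENE09
10	36364594	A	G	REVGENE02
10	43647387	A	C	REVGENE05
11	7579220	T	C	REVGENE02
11	37926179	A	G	REVGENE06
11	42458200	A	C	REVGENE05
12	15300034	A	G	REVGENE03
12	28085385	T	G	REVGENE12
12	31983179	T	G	REVGENE11
13	11322942	T	G	REVGENE10
13	22197581	T	C	REVGENE02
14	5619488	T	C	REVGENE10
15	30259405	A	C	REVGENE03
15	36764448	A	G	REVGENE08
15	42096268	T	C	REVGENE03
16	27470839	T	C	REVGENE06
16	37857334	T	C	REVGENE11
17	32066600	A	G	REVGENE03
18	11258566	A	G	REVGENE09
18	17819241	T	G	REVGENE10
18	30844210	T	G	REVGENE03
18	32740390	T	C	REVGENE12
19	16293429	T	G	REVGENE07
19	25039541	A	G	REVGENE06
20	39463437	T	C	REVGENE06
21	8075605	A	G	REVGENE04
21	43264184	A	C	REVGENE04
21	44146389	T	C	REVGENE06
22	34616495	T	G	REVGENE12
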