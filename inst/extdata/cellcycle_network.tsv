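# Signed coupling matrix of the 11-node budding-yeast cell-cycle Boolean model.
# Rows = target genes, columns = regulators; entries a[i,j] in {-1,0,+1} give the
# influence of gene j on gene i (+1 activating, -1 repressing). The five -1
# diagonal entries encode self-degradation. Synchronous dynamics with the
# tie-keep rule reproduce 7 fixed points (largest basin 1764 of 2048) and the
# 13-state cell-cycle trajectory; see enumerate_attractors()/cellcycle_dataset().
Cln3	MBF	SBF	Cln1,2	Cdh1	Swi5	Cdc20&Cdc14	Clb5,6	Sic1	Clb1,2	Mcm1/SFF
-1	0	0	0	0	0	0	0	0	0	0
1	0	0	0	0	0	0	0	0	-1	0
1	0	0	0	0	0	0	0	0	-1	0
0	0	1	-1	0	0	0	0	0	0	0
0	0	0	-1	0	0	1	-1	0	-1	0
0	0	0	0	0	-1	1	0	0	-1	1
0	0	0	0	0	0	-1	0	0	1	1
0	1	0	0	0	0	-1	0	-1	0	0
0	0	0	-1	0	1	1	-1	0	-1	0
0	0	0	0	-1	0	-1	1	-1	0	1
0	0	0	0	0	0	0	1	0	1	-1
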