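SNP	Y-Position	Mutation	Forward Primer	Reverse Primer	RefSNP ID	Reference
M293	22744939	T to G	GATATTAGTATTGAAGAAACCAG	GCTGGCTAATACTTCCACAGAG	rs9341316	Henn et al. 2008
V16	6851471	C to T	GGTTCAGAATCCTCTGGCACTA	ACAAGAGTTACAAGACCGGGAA	-	present study
V23	6860272	C to A	ATAGCTCATGCTGTTTCTGGT	ACACAGCCAGGATTTCTACCTAGTC	-	present study
V38	6818291	C to T	ATTATTTGAATGCAAGTGGGGA	TGAAACTGAATTAAAGGAAGGTGG	rs768983	present study
V39	16282382	C to G	TTAAAATGGGACCACCAAGAGT	TGCAGAGAGCAAAACTAAATGAA	-	present study
V42	16437344	G to A	CTATAACTGCCTTTCTGCAACATG	TCCCTGCATTTTCTACTCTCAGT	-	present study
V43	16691822	G to T	TGAAGGAGATTTAATTGGGGTAGA	TTTCCATACCATGCCTTTCTTT	rs73621792	present study
V68	17664771	A to C	CAACTGAAAATCAGAACTTTGG	GTGGATCACGAGGTCAGG	-	Cruciani et al. 2010
V92	4873798	C to T	TCTCACTTTCCCCATCCAGA	AGTATTTTATTTTTCCCAAACGTAGC	-	Trombetta et al. 2010
V95	5274968	C to G	TGAAGTGACTGATCTCGTTTCAT	TTGTTAGCCAGAATGGTCTCA	-	Trombetta et al. 2010
V100	5335763	G to A	AATGCTCCTGGTAAATGTTTCT	GCATTTCCTGTTGCCTTT	-	Trombetta et al. 2010
V257	14484546	C to T	CCTCAGGTGGTCATTGCTCTA	CAACAGGAGAAAAGGTGAGAAAC	-	present study
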