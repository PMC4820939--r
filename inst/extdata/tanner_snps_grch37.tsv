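# 13 SNPs associated with male Tanner genital stage, forming the pubertal
# development genetic risk score. Positions are 1-based on GRCh37.p13.
# effect_allele is the Tanner-stage-DECREASING allele (delayed development);
# ref_freq is its frequency in screened population controls.
# weight is the per-allele effect on Tanner stage in Tanner units (positive
# magnitude). NOTE: the published per-allele male Tanner-stage effect sizes
# live in the discovery-GWAS supplements and are not redistributed here; the
# weights below are SYNTHETIC PLACEHOLDERS with field-plausible magnitudes
# (LIN28B strongest), used by the bundled simulator and score arithmetic.
rsid	chrom	pos	effect_allele	other_allele	weight	ref_freq	gene_label
rs2274465	1	44121557	C	G	0.036	0.664	KDM4A
rs6427782	1	199798339	A	G	0.033	0.510	NR5A2 (+198 kb)
rs6762477	3	50093209	A	G	0.030	0.547	RBM6
rs2153127	6	105348544	T	C	0.060	0.530	LIN28B (+36 kb)
rs7759938	6	105378954	C	T	0.080	0.318	LIN28B (+6 kb)
rs7821178	8	78093837	C	A	0.036	0.665	PEX2 (-181 kb)
rs10453225	9	108920220	G	T	0.042	0.681	TMEM38B (-381 kb)
rs2090409	9	108967088	C	A	0.042	0.680	TMEM38B (-428 kb)
rs10739221	9	109060830	C	T	0.048	0.772	TMEM38B (-522 kb)
rs1324913	13	74635588	T	G	0.039	0.338	KLF12
rs12915845	15	89042467	C	T	0.033	0.587	DET1
rs246185	16	14395432	C	T	0.045	0.313	MKL2 (-35 kb)
rs12446632	16	19935389	A	G	0.055	0.146	GPRC5B (-38 kb)
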