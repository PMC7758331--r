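line	class	chrom	arm	tetra_chrom	fl_breakpoint	viability	spike_length	spikelet_number	grain_number	tgw	seed_set	initial_panel
CS	euploid	NA	NA	NA	NA	+	8.2	21.4	63.8	35.3	87.3	TRUE
N1D/T1A	nulli_tetra	1D	NA	1A	NA	-	8.8	23.4	25.2	14.5	43.8	TRUE
N1D/T1B	nulli_tetra	1D	NA	1B	NA	+	8.4	21.4	52.2	29.1	78.9	TRUE
Dt1DS	ditelosomic	1D	S	NA	NA	-	10.4	21.6	18.7	21.0	41.6	TRUE
1DS-5	deletion	1D	S	NA	0.70	+	8.3	19.8	56.2	33.8	82.7	TRUE
1DS-4	deletion	1D	S	NA	0.66	+	9.0	21.0	55.4	32.1	81.7	TRUE
1DS-1	deletion	1D	S	NA	0.59	+	9.1	22.6	45.2	27.5	86.9	TRUE
1DS-2	deletion	1D	S	NA	0.57	+	8.9	22.2	55.6	33.4	89.1	TRUE
1DS-3	deletion	1D	S	NA	0.48	+	8.8	21.8	55.4	31.9	86.7	TRUE
Dt1DL	ditelosomic	1D	L	NA	NA	+	7.5	20.0	31.6	27.2	57.3	TRUE
1DL-4	deletion	1D	L	NA	0.18	-	10.4	21.2	19.0	24.9	51.7	TRUE
1DL-1	deletion	1D	L	NA	0.23	-	11.4	22.0	22.6	19.9	44.4	TRUE
1DL-3	deletion	1D	L	NA	0.25	-	11.2	22.4	30.8	21.8	47.0	TRUE
1DL-6	deletion	1D	L	NA	0.29	-	11.0	21.4	18.6	22.9	39.0	TRUE
CSDt1DSAL	addition	1D	S	NA	NA	+	8.5	22.4	72.0	31.6	91.5	TRUE
1DL-2	deletion	1D	L	NA	0.41	-	NA	NA	NA	NA	NA	FALSE
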