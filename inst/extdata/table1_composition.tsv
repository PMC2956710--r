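library_id	mouse_condition	unfiltered_total	n_bad	tag_types_minus_bad	n_duplicate_ditags	mean_qf	n_below_qf	tag_types_q95	n_ldt_type1	n_ldt_type2	tag_types_final
S1885	13N-AS	310516	955	79201	19761	0.85	63057	52033	124	19	52031
S1886	13N-RAD	318102	1010	96973	12220	0.88	62872	67542	72	9	67540
S1887	13N-CR	339864	1083	99730	12678	0.87	71576	66748	174	54	66746
S1888	15N-AS	338210	1097	81850	21973	0.86	68993	52606	179	56	52604
S1889	15N-RAD	310072	983	84499	17471	0.89	54627	59374	84	33	59372
S1890	15N-CR	326870	737	88249	12836	0.88	54470	64985	186	40	64983
S1891	13R-AS	337546	900	79859	24552	0.88	68981	53715	164	60	53713
S1892	13R-RAD	314440	744	91438	12786	0.80	101215	54682	118	24	54680
S1893	13R-CR	335504	832	90675	13127	0.87	69647	64837	301	59	64835
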