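cell	group	max_speed_cms	rate_lm_mean	rate_lm_sd	rate_sm_mean	rate_sm_sd	rate_ws_mean	rate_ws_sd	rate_im_mean	rate_im_sd	burst_inc_lm_mean	burst_inc_lm_sd	burst_inc_sm_mean	burst_inc_sm_sd	burst_inc_ws_mean	burst_inc_ws_sd	burst_inc_im_mean	burst_inc_im_sd	burst_dur_median_lm	burst_dur_iqr_lm	burst_dur_median_sm	burst_dur_iqr_sm	burst_dur_median_ws	burst_dur_iqr_ws	burst_dur_median_im	burst_dur_iqr_im	ks_p_dur_lm_im	ibi_median_lm	ibi_iqr_lm	ibi_median_sm	ibi_iqr_sm	ibi_median_ws	ibi_iqr_ws	ibi_median_im	ibi_iqr_im	ks_p_ibi_lm_im	intra_lm_mean	intra_lm_sd	intra_sm_mean	intra_sm_sd	intra_ws_mean	intra_ws_sd	intra_im_mean	intra_im_sd	ks_p_intra_lm_im	theta_phase_deg	theta_r	theta_p	theta_n	spikes_per_cycle_mean	spikes_per_cycle_sd	gamma_phase_deg	gamma_r	gamma_p	gamma_n	n_swr	swr_rate_inside	swr_lambda_outside	swr_p
TV58g	identified_orchid	u	48.4	6.0	41.6	5.3	47.1	9.3	44.2	12.0	5.0	1.0	4.4	0.5	4.4	0.9	4.2	1.2	87.0	79.8	86.7	47.5	91.8	77.1	94.6	65.5	0.5928	187.7	80.9	214.2	81.2	205.1	100.3	203.3	94.5	0.0725	95.9	22.1	84.9	19.5	96.6	24.3	94.7	22.8	0.3102	159	0.37	0.0001	1081	6.8	3.1	u	u	u	u	34	57.08	44.82	0.0181
TV50a	identified_orchid	u	51.4	10.6	47.6	8.8	u	u	46.3	10.5	6.3	0.9	5.7	1.0	u	u	5.0	0.9	66.8	30.5	71.0	42.0	u	u	70.2	46.0	0.0021	146.0	35.2	159.9	49.3	u	u	177.3	92.3	0.0001	111.4	24.8	105.7	24.5	u	u	113.1	34.0	0.0693	176	0.50	0.0001	2679	6.7	3.0	u	u	0.0860	1240	40	31.37	49.14	0.0015
MS14i	identified_orchid	6.3	67.8	12.9	51.0	12.7	47.9	9.0	48.2	10.0	3.8	1.7	4.7	1.1	4.6	1.1	4.9	0.9	121.0	193.0	84.2	56.7	91.7	61.5	81.1	48.9	0.0001	179.6	162.5	178.7	99.1	189.9	105.1	180.3	87.5	0.0039	95.8	24.4	99.7	30.0	93.1	24.3	100.6	28.0	0.0357	152	0.23	0.0001	6659	8.7	4.2	164	0.04	0.0008	3553	57	57.71	48.96	0.0238
MS19b	identified_orchid	18.8	43.4	9.3	33.3	8.6	33.2	8.0	31.9	5.2	4.4	0.9	3.6	1.1	4.4	1.3	4.5	1.3	96.2	57.5	85.7	53.4	92.0	56.8	100.0	57.3	0.6573	193.5	91.8	230.1	166.5	255.4	180.0	238.3	161.8	0.0001	83.7	24.6	82.8	27.5	80.7	22.7	77.6	19.7	0.0180	167	0.27	0.0001	5143	7.2	3.4	158	0.25	0.0001	2052	58	4.88	33.16	0.0001
AJ50j	identified_orchid	17.2	65.3	11.7	42.5	9.7	34.7	6.1	46.6	9.9	6.7	1.0	5.5	1.3	4.6	1.0	5.4	1.0	63.2	22.6	54.0	23.8	59.2	30.2	57.8	33.3	0.0003	135.8	41.3	159.9	66.1	178.1	137.8	163.3	66.2	0.0001	136.1	27.2	121.0	27.2	110.6	27.4	124.0	32.6	0.0001	177	0.51	0.0001	1743	7.2	3.1	u	u	0.6225	1445	0	u	u	u
AJ50h	identified_orchid	16.5	33.6	9.6	27.7	3.8	24.3	4.9	25.4	7.6	4.1	1.7	3.3	0.8	2.8	0.8	3.1	1.3	70.1	36.3	65.2	56.3	68.3	35.5	73.9	33.7	0.3998	160.0	148.9	257.6	209.6	291.7	315.5	255.8	201.0	0.0001	75.9	23.6	79.2	17.7	71.8	10.2	78.1	16.8	0.0602	264	0.35	0.0001	1413	4.6	1.9	191	0.19	0.0001	398	0	u	u	u
AJ44j	identified_orchid	12.0	76.7	11.0	43.8	9.9	37.7	2.5	38.1	6.8	6.2	1.9	5.6	1.2	6.0	1.0	5.3	1.1	68.2	48.9	70.1	38.3	52.4	30.3	68.6	42.7	0.1947	129.0	52.1	158.2	67.6	157.3	73.9	161.5	61.7	0.0001	131.4	30.9	96.0	24.5	96.4	13.6	89.3	18.2	0.0001	130	0.44	0.0001	860	7.7	3.3	u	u	0.0799	579	0	u	u	u
MS74b	identified_orchid	u	55.0	11.0	u	u	34.2	14.9	37.6	16.0	5.2	1.3	u	u	2.9	1.4	3.5	0.9	80.1	40.1	u	u	91.5	91.9	97.0	75.0	0.0293	155.3	86.4	u	u	254.5	229.1	249.0	135.2	0.0001	95.2	20.2	u	u	75.6	16.1	79.3	22.9	0.0001	233	0.34	0.0001	578	8.1	3.2	u	u	0.4700	437	16	u	u	u
MS17k	putative_orchid	9.9	51.6	25.5	51.8	13.8	46.7	13.0	44.6	13.8	3.3	2.2	4.7	1.0	4.7	1.3	4.3	1.2	86.7	115.8	90.8	84.8	82.9	74.0	84.4	67.7	0.3902	166.6	155.2	190.7	135.2	197.9	95.7	201.8	117.9	0.0484	103.4	35.6	94.2	28.5	95.6	38.8	95.0	27.3	0.0914	176	0.29	0.0001	727	9.0	3.7	u	u	0.1919	1003	24	69.35	46.33	0.0004
MS58i	putative_orchid	u	80.9	20.2	42.3	9.1	52.1	14.7	52.1	14.7	6.6	1.0	4.9	1.4	u	u	4.9	1.1	70.2	22.0	67.3	47.2	76.7	57.4	76.7	57.4	0.0024	133.1	31.1	169.8	117.3	u	u	170.7	100.1	0.0001	141.9	24.7	101.9	26.1	u	u	101.9	30.3	0.0001	133	0.42	0.0001	2869	7.6	3.9	u	u	0.6089	1032	6	u	u	u
MS24a	putative_orchid	16.8	48.7	10.7	50.1	11.7	44.2	11.5	33.7	8.8	5.3	1.4	4.0	0.9	3.4	1.0	3.3	1.2	57.4	36.8	107.0	84.0	97.3	65.1	94.1	73.0	0.0001	155.6	96.5	236.9	138.7	259.9	194.5	260.7	186.0	0.0001	144.3	46.8	104.4	35.8	97.8	25.9	82.5	27.4	0.0001	178	0.43	0.0001	3287	6.8	3.9	155	0.3210	0.0001	284	55	27.47	36.92	0.0176
MS84f	putative_orchid	u	65.2	7.5	56.0	10.9	48.9	11.6	48.4	9.2	5.1	1.5	4.6	1.4	4.8	1.3	4.8	1.1	86.4	111.8	99.2	77.6	96.7	93.0	94.3	69.9	0.0294	147.4	115.9	178.1	86.8	189.1	92.9	187.2	88.1	0.0001	105.1	23.8	89.3	27.0	88.9	24.2	86.9	22.7	0.0001	177	0.31	0.0001	4624	8.8	2.7	u	u	0.0870	1227	0	u	u	u
TV78d	putative_orchid	14.3	31.5	11.9	41.6	18.3	u	u	39.5	9.8	3.6	1.3	4.0	1.1	u	u	3.8	1.0	76.9	39.4	90.0	57.6	u	u	95.3	72.1	0.0001	197.8	163.9	206.6	136.8	u	u	238.1	136.9	0.0001	83.3	22.9	87.4	22.8	u	u	89.4	27.2	0.0449	261	0.38	0.0001	2154	5.3	3.4	144	0.12	0.0001	871	24	3.75	40.71	0.0001
TV78k	putative_orchid	4.5	60.6	12.5	34.4	12.1	30.3	15.5	33.6	9.6	3.6	1.0	3.3	0.9	2.8	1.0	3.3	1.0	156.3	101.6	112.9	70.2	118.3	50.0	112.6	72.3	0.0001	233.8	155.6	267.4	163.5	311.2	299.0	267.6	137.6	0.0130	81.8	17.9	68.0	14.6	70.8	17.8	72.4	19.8	0.0001	163	0.26	0.0001	1291	7.5	4.1	u	u	0.3506	1457	46	19.67	31.92	0.0068
TV85e	putative_orchid	u	87.6	14.9	47.3	14.3	50.1	10.1	58.0	13.0	7.0	1.4	5.2	1.5	5.4	1.1	5.3	1.1	64.1	34.0	62.5	25.9	62.1	43.4	65.9	45.1	0.5547	133.0	32.1	163.1	73.2	159.7	79.0	159.9	91.8	0.0001	150.2	32.8	117.9	28.2	118.2	26.9	135.5	39.0	0.0003	160	0.41	0.0001	2792	7.3	4.4	207	0.04	0.0417	2000	19	u	u	u
TV86b	putative_orchid	u	67.9	9.1	49.5	6.4	55.1	9.3	37.0	9.7	5.3	1.2	5.0	0.0	u	u	u	u	89.6	62.7	101.2	77.0	96.5	70.3	75.8	43.4	0.0045	163.1	91.8	181.8	84.8	185.4	95.3	194.4	113.2	0.0001	119.4	32.4	96.3	24.6	105.0	26.8	96.3	25.4	0.0001	243	0.30	0.0001	1292	9.6	3.6	u	u	0.4627	1274	42	4.48	42.31	0.0001
TV77q	septohippocampal	u	38.4	12.2	22.5	7.6	16.0	7.5	15.6	8.1	3.7	1.4	2.6	0.9	1.5	1.1	1.5	1.2	69.7	73.6	75.9	40.5	74.3	38.6	69.0	48.1	u	196.6	206.7	332.0	250.9	427.4	588.3	445.5	615.9	u	85.3	27.1	78.1	28.3	82.9	27.2	85.7	31.1	u	230	0.27	0.0001	1206	3.1	2.7	u	u	u	u	50	6.20	16.05	0.0025
TV78l	septohippocampal	u	25.3	1.7	16.7	5.8	23.3	8.6	21.6	6.2	2.5	0.6	1.5	1.2	1.3	1.2	1.8	1.2	85.9	96.2	64.9	19.6	109.3	102.4	86.3	60.5	u	537.7	412.8	457.3	418.8	427.3	214.8	393.4	384.6	u	69.8	35.9	65.6	15.9	69.3	13.3	64.1	15.6	u	u	u	0.2819	505	u	u	u	u	u	u	61	0.65	21.73	0.0001
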