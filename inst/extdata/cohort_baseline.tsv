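variable	mean_short	sd_short	n_short	mean_long	sd_long	n_long
age_years	77.42	2.22	24	77.04	0.91	24
bmi	24.09	4.18	24	26.36	4.68	24
red_blood_cells_1e6_mm3	4.31	0.74	24	4.53	0.66	24
platelets_1e3_mm3	213.67	51.77	24	243.96	68.75	24
white_blood_cells_1e3_mm3	6.20	2.52	24	6.22	1.90	24
neutrophils_1e3_mm3	4.24	2.37	24	3.82	1.72	24
lymphocytes_1e3_mm3	1.48	0.51	24	1.93	0.59	24
monocytes_1e3_mm3	0.31	0.11	24	0.34	0.16	24
eosinophils_1e3_mm3	0.14	0.13	24	0.11	0.08	24
basophils_1e3_mm3	0.04	0.05	24	0.03	0.04	24
neutrophils_pct	65.8	9.5	24	60.0	9.0	24
lymphocytes_pct	25.8	8.4	24	31.92	7.8	24
monocytes_pct	5.5	2.5	24	5.9	2.3	24
eosinophils_pct	2.5	2.9	24	1.8	1.5	24
basophils_pct	0.5	0.5	24	0.3	0.5	24
neutrophil_lymphocyte_ratio_counts	3.2	2.5	24	2.1	1.0	24
neutrophil_lymphocyte_ratio_pct	3.2	2.4	24	2.1	1.0	24
iadl_cognitive_items	2.4	0.9	24	2.9	0.3	24
iadl_motor_items	2.4	1.9	24	3.8	0.7	24
rosow_breslau_heavy_housework	1.5	0.5	24	1.9	0.3	24
rosow_breslau_stairs	1.6	0.5	24	1.9	0.3	24
rosow_breslau_half_mile	1.5	0.5	24	2.0	0.2	24
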