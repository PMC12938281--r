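subject	csp_lda	csp_svm	csp_mlp	dfbcsp_lda	dfbcsp_svm	dfbcsp_mlp
S1	76.41	76.85	79.37	82.51	82.94	85.73
S2	76.62	78.39	81.54	80.23	81.76	86.41
S3	78.83	81.49	83.71	82.74	84.61	88.25
S4	63.59	65.64	70.28	71.35	74.24	79.13
S5	77.42	76.83	79.41	81.54	83.62	84.39
S6	68.51	71.45	74.84	75.69	80.37	83.46
S7	67.27	70.60	73.16	74.37	77.82	82.37
S8	73.39	76.31	79.52	81.25	85.39	90.29
S9	80.31	79.87	81.33	79.91	80.17	85.57
S10	69.84	74.62	79.25	80.34	83.51	87.64
S11	78.25	81.13	83.61	87.58	89.77	92.74
S12	67.43	69.57	74.25	78.36	83.04	85.36
S13	79.22	78.46	80.34	79.77	85.27	87.18
S14	68.31	70.35	75.43	79.85	80.79	84.74
S15	66.58	69.71	71.76	76.97	79.64	83.53
S16	81.47	82.79	84.39	87.79	91.57	92.48
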