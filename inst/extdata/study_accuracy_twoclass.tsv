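subject	csp_lda	csp_svm	csp_mlp	dfbcsp_lda	dfbcsp_svm	dfbcsp_mlp
S1	92.57	93.64	92.78	94.27	96.36	98.75
S2	87.62	92.33	93.46	91.75	92.05	95.28
S3	83.14	84.51	86.30	85.27	91.94	95.48
S4	74.95	79.25	81.37	84.62	87.45	91.87
S5	78.38	80.34	83.61	86.45	89.83	93.24
S6	81.82	82.74	83.54	86.21	90.59	93.66
S7	84.57	85.49	84.92	87.73	89.47	94.08
S8	86.48	88.73	91.23	91.39	93.76	97.34
S9	79.56	81.46	81.77	84.69	87.51	92.57
S10	85.79	87.34	88.42	90.94	91.76	94.84
S11	84.63	86.85	85.68	88.64	92.45	95.18
S12	80.62	83.05	85.41	84.75	87.68	93.71
S13	82.37	83.77	84.37	85.76	90.16	94.14
S14	79.74	81.19	82.64	84.98	88.78	93.71
S15	85.31	88.54	89.79	90.29	93.46	96.59
S16	89.48	90.62	91.34	92.44	92.97	96.87
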