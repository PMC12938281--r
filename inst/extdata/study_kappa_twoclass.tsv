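subject	csp_lda	csp_svm	csp_mlp	dfbcsp_lda	dfbcsp_svm	dfbcsp_mlp
S1	0.734	0.749	0.777	0.798	0.826	0.861
S2	0.652	0.687	0.712	0.762	0.857	0.906
S3	0.738	0.767	0.786	0.817	0.834	0.875
S4	0.631	0.685	0.725	0.785	0.821	0.881
S5	0.702	0.714	0.742	0.783	0.832	0.893
S6	0.655	0.697	0.721	0.794	0.836	0.884
S7	0.724	0.741	0.793	0.824	0.857	0.912
S8	0.708	0.722	0.761	0.811	0.852	0.896
S9	0.687	0.713	0.748	0.787	0.838	0.892
S10	0.741	0.789	0.814	0.861	0.892	0.921
S11	0.722	0.753	0.792	0.824	0.871	0.931
S12	0.652	0.686	0.727	0.765	0.813	0.856
S13	0.665	0.714	0.734	0.767	0.807	0.867
S14	0.737	0.751	0.781	0.812	0.846	0.878
S15	0.648	0.687	0.716	0.758	0.818	0.863
S16	0.711	0.769	0.810	0.835	0.875	0.924
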