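subject	csp_lda	csp_svm	csp_mlp	dfbcsp_lda	dfbcsp_svm	dfbcsp_mlp
S1	0.647	0.659	0.690	0.719	0.726	0.772
S2	0.594	0.627	0.658	0.703	0.739	0.793
S3	0.615	0.643	0.674	0.712	0.725	0.759
S4	0.462	0.524	0.602	0.637	0.693	0.757
S5	0.544	0.603	0.614	0.633	0.688	0.762
S6	0.623	0.648	0.696	0.722	0.747	0.806
S7	0.493	0.544	0.618	0.627	0.651	0.734
S8	0.484	0.527	0.609	0.635	0.662	0.748
S9	0.513	0.572	0.624	0.674	0.713	0.771
S10	0.537	0.571	0.618	0.662	0.710	0.763
S11	0.521	0.593	0.629	0.668	0.734	0.788
S12	0.473	0.542	0.617	0.649	0.681	0.734
S13	0.583	0.615	0.654	0.714	0.762	0.815
S14	0.647	0.673	0.708	0.728	0.753	0.803
S15	0.524	0.568	0.628	0.691	0.737	0.807
S16	0.497	0.557	0.610	0.677	0.721	0.784
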