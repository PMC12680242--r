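top_pct	K	algorithm	smoothing	additive	dominant	recessive	epistatic
1	5530	saliency	no	1.00	0.99	0.15	0.20
1	5530	saliency	yes	1.00	0.99	0.16	0.20
1	5530	gradient_shap	no	1.00	0.40	0.01	0.20
1	5530	gradient_shap	yes	1.00	0.99	0.24	0.21
1	5530	deeplift	no	1.00	0.39	0.01	0.20
1	5530	deeplift	yes	1.00	0.99	0.24	0.21
1	5530	integrated_gradients	no	1.00	0.39	0.01	0.20
1	5530	integrated_gradients	yes	1.00	0.99	0.24	0.21
1	5530	gwas	no	1.00	0.83	0.00	0.00
5	27650	saliency	no	1.00	1.00	0.47	0.23
5	27650	saliency	yes	1.00	1.00	0.47	0.23
5	27650	gradient_shap	no	1.00	0.95	0.35	0.25
5	27650	gradient_shap	yes	1.00	1.00	0.48	0.27
5	27650	deeplift	no	1.00	0.94	0.35	0.25
5	27650	deeplift	yes	1.00	1.00	0.48	0.27
5	27650	integrated_gradients	no	1.00	0.95	0.35	0.25
5	27650	integrated_gradients	yes	1.00	1.00	0.48	0.27
5	27650	gwas	no	1.00	1.00	0.16	0.00
10	55300	saliency	no	1.00	1.00	0.56	0.28
10	55300	saliency	yes	1.00	1.00	0.55	0.28
10	55300	gradient_shap	no	1.00	1.00	0.44	0.34
10	55300	gradient_shap	yes	1.00	1.00	0.56	0.34
10	55300	deeplift	no	1.00	0.99	0.44	0.35
10	55300	deeplift	yes	1.00	1.00	0.55	0.34
10	55300	integrated_gradients	no	1.00	1.00	0.44	0.34
10	55300	integrated_gradients	yes	1.00	1.00	0.56	0.34
10	55300	gwas	no	1.00	1.00	0.44	0.02
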