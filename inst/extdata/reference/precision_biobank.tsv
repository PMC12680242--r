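algorithm	smoothing	top20	top10	top5	top3	top2	top1
saliency	no	0.3553	0.5050	0.6451	0.7438	0.8146	0.9159
saliency	yes	0.3557	0.5055	0.6461	0.7436	0.8148	0.9165
gradient_shap	no	0.2363	0.3682	0.4971	0.5887	0.6589	0.7680
gradient_shap	yes	0.3282	0.4681	0.5921	0.6814	0.7524	0.8493
deeplift	no	0.2364	0.3678	0.4970	0.5897	0.6591	0.7681
deeplift	yes	0.3286	0.4684	0.5932	0.6829	0.7507	0.8511
integrated_gradients	no	0.2363	0.3682	0.4970	0.5887	0.6588	0.7678
integrated_gradients	yes	0.3282	0.4678	0.5917	0.6816	0.7519	0.8491
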