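algorithm	smoothing	median_rsd	mad_scaled
saliency	no	0.38294	0.11644
saliency	yes	0.41311	0.14581
gradient_shap	no	0.45137	0.15829
gradient_shap	yes	0.42609	0.14209
deeplift	no	0.45597	0.16199
deeplift	yes	0.42586	0.14453
integrated_gradients	no	0.45681	0.16379
integrated_gradients	yes	0.42971	0.14547
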