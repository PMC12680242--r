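algorithm	smoothing	recall_top1	precision_top1	consistency	composite
saliency	no	0.5850	0.9159	0.5378	0.6605
saliency	yes	0.5875	0.9165	0.5121	0.6509
gradient_shap	no	0.4025	0.7680	0.4813	0.5299
gradient_shap	yes	0.6100	0.8493	0.5015	0.6381
deeplift	no	0.4000	0.7681	0.4778	0.5275
deeplift	yes	0.6100	0.8511	0.5017	0.6386
integrated_gradients	no	0.4000	0.7678	0.4771	0.5272
integrated_gradients	yes	0.6100	0.8491	0.4985	0.6368
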