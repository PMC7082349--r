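feature,univariate_auc,pearson_p,coefficient
Coiflet_LLL_GLSZM_zone_percentage,0.683,0.003,0.445876806974411
Coiflet_LLH_NGTDM_contrast,0.650,0.029,0.135681539773941
Coiflet_LHL_GLCM_maximum_probability,0.685,0.023,0.336605042219162
location_chebyshev,0.656,0.032,0.281620532274246
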