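tissue,auc_pred,auc_obs,unit
plasma,87505,70799,h*nmol/L
testis,1495,1355,h*nmol/L
epididymis,2253,1988,h*nmol/L
seminal_vesicle,369,355,h*nmol/L
vas_deferens,1757,1783,h*nmol/L
prostate_gland,423,436,h*nmol/L
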