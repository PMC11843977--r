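parameter,value,unit,source
kon_FcRn,8.06e7,1/(M*h),synthetic_representative
koff_FcRn,6.55,1/h,synthetic_representative
kdeg,26.6,1/h,synthetic_representative
FR,0.715,dimensionless,synthetic_representative
CLup_endothelium,0.55,L/h/L,synthetic_representative
FcRn_endothelium,4.98e-5,M,literature_anchor
FcRn_BTB,4.98e-6,M,literature_anchor
sigma_vascular_default,0.95,dimensionless,synthetic_representative
sigma_vascular_brain,0.99,dimensionless,synthetic_representative
sigma_interstitial_default,0.2,dimensionless,synthetic_representative
sigma_epithelial_default,0.95,dimensionless,assumption
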