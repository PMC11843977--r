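species,organ,field,value,unit,source
mouse,plasma,total_volume,9.44e-4,L,synthetic_representative
mouse,blood_cell,total_volume,7.73e-4,L,synthetic_representative
mouse,lymph_node,total_volume,1.13e-4,L,synthetic_representative
mouse,heart,total_volume,1.52e-4,L,synthetic_representative
mouse,heart,vascular_volume,7.6e-6,L,synthetic_representative
mouse,heart,interstitial_volume,2.5e-5,L,synthetic_representative
mouse,heart,plasma_flow,0.0304,L/h,synthetic_representative
mouse,heart,blood_cell_flow,0.0249,L/h,synthetic_representative
mouse,kidney,total_volume,5.25e-4,L,synthetic_representative
mouse,kidney,vascular_volume,5.25e-5,L,synthetic_representative
mouse,kidney,interstitial_volume,7.9e-5,L,synthetic_representative
mouse,kidney,plasma_flow,0.0601,L/h,synthetic_representative
mouse,kidney,blood_cell_flow,0.0492,L/h,synthetic_representative
mouse,muscle,total_volume,1.13e-2,L,synthetic_representative
mouse,muscle,vascular_volume,2.26e-4,L,synthetic_representative
mouse,muscle,interstitial_volume,1.47e-3,L,synthetic_representative
mouse,muscle,plasma_flow,0.0733,L/h,synthetic_representative
mouse,muscle,blood_cell_flow,0.0600,L/h,synthetic_representative
mouse,skin,total_volume,5.02e-3,L,synthetic_representative
mouse,skin,vascular_volume,1.0e-4,L,synthetic_representative
mouse,skin,interstitial_volume,1.51e-3,L,synthetic_representative
mouse,skin,plasma_flow,0.0267,L/h,synthetic_representative
mouse,skin,blood_cell_flow,0.0218,L/h,synthetic_representative
mouse,brain,total_volume,4.85e-4,L,synthetic_representative
mouse,brain,vascular_volume,1.46e-5,L,synthetic_representative
mouse,brain,interstitial_volume,8.7e-6,L,synthetic_representative
mouse,brain,plasma_flow,0.0152,L/h,synthetic_representative
mouse,brain,blood_cell_flow,0.0124,L/h,synthetic_representative
mouse,adipose,total_volume,1.98e-3,L,synthetic_representative
mouse,adipose,vascular_volume,2.0e-5,L,synthetic_representative
mouse,adipose,interstitial_volume,3.3e-4,L,synthetic_representative
mouse,adipose,plasma_flow,0.0182,L/h,synthetic_representative
mouse,adipose,blood_cell_flow,0.0149,L/h,synthetic_representative
mouse,thymus,total_volume,3.0e-5,L,synthetic_representative
mouse,thymus,vascular_volume,1.5e-6,L,synthetic_representative
mouse,thymus,interstitial_volume,5.4e-6,L,synthetic_representative
mouse,thymus,plasma_flow,6.6e-4,L/h,synthetic_representative
mouse,thymus,blood_cell_flow,5.4e-4,L/h,synthetic_representative
mouse,liver,total_volume,1.93e-3,L,synthetic_representative
mouse,liver,vascular_volume,1.93e-4,L,synthetic_representative
mouse,liver,interstitial_volume,3.86e-4,L,synthetic_representative
mouse,liver,plasma_flow,0.00924,L/h,synthetic_representative
mouse,liver,blood_cell_flow,0.00756,L/h,synthetic_representative
mouse,spleen,total_volume,1.27e-4,L,synthetic_representative
mouse,spleen,vascular_volume,2.54e-5,L,synthetic_representative
mouse,spleen,interstitial_volume,2.54e-5,L,synthetic_representative
mouse,spleen,plasma_flow,0.00429,L/h,synthetic_representative
mouse,spleen,blood_cell_flow,0.00351,L/h,synthetic_representative
mouse,pancreas,total_volume,9.7e-5,L,synthetic_representative
mouse,pancreas,vascular_volume,4.9e-6,L,synthetic_representative
mouse,pancreas,interstitial_volume,1.7e-5,L,synthetic_representative
mouse,pancreas,plasma_flow,0.00594,L/h,synthetic_representative
mouse,pancreas,blood_cell_flow,0.00486,L/h,synthetic_representative
mouse,small_intestine,total_volume,7.3e-4,L,synthetic_representative
mouse,small_intestine,vascular_volume,3.65e-5,L,synthetic_representative
mouse,small_intestine,interstitial_volume,1.39e-4,L,synthetic_representative
mouse,small_intestine,plasma_flow,0.0495,L/h,synthetic_representative
mouse,small_intestine,blood_cell_flow,0.0405,L/h,synthetic_representative
mouse,large_intestine,total_volume,3.1e-4,L,synthetic_representative
mouse,large_intestine,vascular_volume,1.55e-5,L,synthetic_representative
mouse,large_intestine,interstitial_volume,5.9e-5,L,synthetic_representative
mouse,large_intestine,plasma_flow,0.0175,L/h,synthetic_representative
mouse,large_intestine,blood_cell_flow,0.0143,L/h,synthetic_representative
mouse,bone,total_volume,2.82e-3,L,synthetic_representative
mouse,bone,vascular_volume,8.5e-5,L,synthetic_representative
mouse,bone,interstitial_volume,5.6e-4,L,synthetic_representative
mouse,bone,plasma_flow,0.0508,L/h,synthetic_representative
mouse,bone,blood_cell_flow,0.0416,L/h,synthetic_representative
mouse,lung,total_volume,2.04e-4,L,synthetic_representative
mouse,lung,vascular_volume,6.1e-5,L,synthetic_representative
mouse,lung,interstitial_volume,3.9e-5,L,synthetic_representative
mouse,other,total_volume,1.35e-3,L,synthetic_representative
mouse,other,vascular_volume,6.8e-5,L,synthetic_representative
mouse,other,interstitial_volume,2.7e-4,L,synthetic_representative
mouse,other,plasma_flow,0.033,L/h,synthetic_representative
mouse,other,blood_cell_flow,0.027,L/h,synthetic_representative
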