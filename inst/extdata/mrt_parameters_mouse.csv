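parameter,estimate,se,cv_percent,unit
CLup_BTB,6.78e-2,4.30e-6,6.34e-3,L/h/L
CLup_E_testis,1.27e2,4.10e-5,3.23e-5,L/h/L
Q_retetestis,1.20e-8,3.40e-8,2.83e2,L/h
Q_ep,1.60e-4,1.10e-4,6.88e1,L/h
Q_vd,2.00e-5,1.90e-6,9.50,L/h
Q_sv,9.40e-5,1.20e-5,1.28e1,L/h
Q_pg,1.60e-5,8.60e-7,5.38,L/h
BEB_volume,2.80e-4,4.00e-5,1.43e1,L
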