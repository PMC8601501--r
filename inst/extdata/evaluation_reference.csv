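period,attribute,units,n,rmse,me,nrmse_pct,rme_pct,d,consistent
calibration,anthesis,d,2,2.55,2.50,1.71,1.67,0.99,TRUE
calibration,maturity,d,2,3.16,3.00,1.48,1.41,0.99,TRUE
calibration,yield,kg/ha,2,256.19,236.50,9.96,9.20,0.72,FALSE
calibration,biomass,kg/ha,2,1109.87,-1075.00,9.63,-9.33,0.99,TRUE
evaluation,anthesis,d,3,2.08,1.67,1.37,1.10,1.00,TRUE
evaluation,maturity,d,3,2.16,2.00,1.01,0.93,1.00,TRUE
evaluation,yield,kg/ha,3,137.37,67.33,4.94,2.42,0.87,TRUE
evaluation,biomass,kg/ha,3,1015.42,-315.33,8.91,-2.77,0.99,TRUE
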