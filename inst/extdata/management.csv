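site,soil_type,planting_date,row_spacing_cm,population_plants_m2,n_rate_kg_ha
Luxi,Red soil,2018-09-20,25,45,174
Chongqing,Red soil,2018-09-28,25,45,174
Hanzhong,Paddy soil,2018-09-26,25,45,174
Zhuzhou,Yellow brown soil,2018-09-28,25,45,174
Wuhu,Paddy soil,2018-10-01,25,45,174
Gaoyou,Paddy soil,2018-10-03,25,45,174
Hangzhou,Red soil,2018-10-05,25,45,174
Wuhan,Yellow brown soil,2018-09-28,25,45,174
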