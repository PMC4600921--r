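country,gender,ethnicity,height_alpha,height_a1,height_a2,height_sigma,logbm_alpha,logbm_a1,logbm_a2,logbm_sigma,rho_height_logbm,co_alpha,co_h1,co_a1,co_a2,co_a3,co_sigma
UK,male,White,176.0,0.15,-0.003,6.9,4.06,0.0168,-0.00017,0.17,0.41,2.755,0.025,-0.030,-0.707,-0.626,0.109
UK,male,Asian,174.4,-0.086,0,6.3,3.96,0.0186,-0.00021,0.18,0.42,2.748,0.026,-0.031,-0.513,-0.716,0.108
UK,male,Black,178.8,-0.113,0,7.4,4.10,0.0167,-0.0002,0.19,0.45,2.645,0.026,-0.029,-0.399,-0.934,0.110
UK,female,White,163.9,0.052,-0.0017,6.3,4.00,0.0099,-0.00009,0.20,0.29,1.870,0.0246,0.0122,-0.000908,0.00000689,0.093
UK,female,Asian,162.0,-0.126,0,6.0,3.94,0.009,-0.00007,0.20,0.29,1.703,0.0257,0.0173,-0.000916,0.00000642,0.093
UK,female,Black,161.9,0.228,-0.0049,6.3,3.93,0.0147,-0.00013,0.19,0.36,1.893,0.0248,0.0090,-0.000869,0.00000689,0.093
US,male,White,175.6,0.136,-0.002,6.6,3.96,0.0197,-0.00020,0.19,0.43,2.749,0.025,-0.031,-0.449,-0.820,0.110
US,male,Hispanic,171.0,-0.03,0,6.4,3.86,0.0226,-0.00024,0.18,0.44,2.781,0.026,-0.031,-0.458,-0.828,0.109
US,male,Black,172.4,0.267,-0.0038,7.0,3.92,0.0233,-0.00026,0.22,0.28,2.342,0.026,-0.031,0.403,0.917,0.111
US,female,White,162.1,0.142,-0.0025,6.3,3.88,0.014,-0.00012,0.22,0.31,1.854,0.0248,0.0127,-0.000956,0.00000739,0.092
US,female,Hispanic,159.3,-0.066,0,6.0,3.79,0.020,-0.00021,0.21,0.29,1.792,0.0257,0.0166,-0.001015,0.00000765,0.092
US,female,Black,162.3,0.108,-0.0019,6.4,3.87,0.020,-0.0002,0.25,0.46,1.903,0.0246,0.0088,-0.000839,0.00000625,0.093
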