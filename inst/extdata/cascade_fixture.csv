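subject_id,timepoint,age,sex,BMI,HbA1c,glucose,insulin,HOMA_IR,eGFR,clin_0001,prot_A,prot_B,met_bad,met_A,met_B,met_C,met_D,met_E,met_F,met_G,met_H,met_I,met_J
S01,t0,50,0,27,5.5,90,10,2.2222222222222223,90,1,0.5,0.69999999999999996,0.10000000000000001,0.20000000000000001,0.30000000000000004,0.40000000000000002,0.5,0.60000000000000009,0.70000000000000007,0.80000000000000004,0.90000000000000002,1,1.1000000000000001
S02,t0,50,0,27,5.5,90,10,2.2222222222222223,90,1,0.5,0.69999999999999996,0.10000000000000001,0.20000000000000001,0.30000000000000004,0.40000000000000002,0.5,0.60000000000000009,0.70000000000000007,0.80000000000000004,0.90000000000000002,1,1.1000000000000001
S03,t0,50,0,27,5.5,90,10,2.2222222222222223,90,1,0.5,0.69999999999999996,0.10000000000000001,0.20000000000000001,0.30000000000000004,0.40000000000000002,0.5,0.60000000000000009,0.70000000000000007,0.80000000000000004,0.90000000000000002,1,1.1000000000000001
S04,t0,50,0,27,5.5,90,10,2.2222222222222223,90,1,0.5,0.69999999999999996,,0.20000000000000001,0.30000000000000004,0.40000000000000002,0.5,,0.70000000000000007,0.80000000000000004,0.90000000000000002,1,1.1000000000000001
S05,t0,50,0,27,5.5,90,10,2.2222222222222223,90,1,0.5,0.69999999999999996,,,0.30000000000000004,0.40000000000000002,,0.60000000000000009,0.70000000000000007,0.80000000000000004,0.90000000000000002,1,1.1000000000000001
S06,t0,50,0,27,5.5,90,10,2.2222222222222223,90,1,,0.69999999999999996,0.10000000000000001,0.20000000000000001,0.30000000000000004,0.40000000000000002,0.5,0.60000000000000009,0.70000000000000007,0.80000000000000004,0.90000000000000002,1,1.1000000000000001
S07,t0,50,0,27,5.5,90,10,2.2222222222222223,90,1,0.5,0.69999999999999996,0.10000000000000001,0.20000000000000001,0.30000000000000004,0.40000000000000002,0.5,0.60000000000000009,0.70000000000000007,0.80000000000000004,0.90000000000000002,1,1.1000000000000001
S08,t0,50,0,27,5.5,90,10,2.2222222222222223,90,1,0.5,0.69999999999999996,0.10000000000000001,0.20000000000000001,0.30000000000000004,0.40000000000000002,0.5,0.60000000000000009,0.70000000000000007,0.80000000000000004,0.90000000000000002,1,1.1000000000000001
S01,t1,50,0,27,5.4000000000000004,92,11,2.4987654320987653,89,1.1000000000000001,0.5,0.69999999999999996,0.11,0.21000000000000002,0.31000000000000005,0.41000000000000003,0.51000000000000001,0.6100000000000001,0.71000000000000008,0.81000000000000005,0.91000000000000003,1.01,1.1100000000000001
S03,t1,50,0,27,,92,11,2.4987654320987653,89,1.1000000000000001,0.5,0.69999999999999996,0.11,0.21000000000000002,0.31000000000000005,0.41000000000000003,0.51000000000000001,0.6100000000000001,0.71000000000000008,0.81000000000000005,0.91000000000000003,1.01,1.1100000000000001
S04,t1,50,0,27,5.4000000000000004,92,11,2.4987654320987653,89,1.1000000000000001,0.5,0.69999999999999996,,0.21000000000000002,0.31000000000000005,0.41000000000000003,0.51000000000000001,0.6100000000000001,0.71000000000000008,0.81000000000000005,0.91000000000000003,1.01,1.1100000000000001
S05,t1,50,0,27,5.4000000000000004,92,11,2.4987654320987653,89,1.1000000000000001,0.5,0.69999999999999996,0.11,0.21000000000000002,,0.41000000000000003,0.51000000000000001,0.6100000000000001,0.71000000000000008,0.81000000000000005,0.91000000000000003,1.01,1.1100000000000001
S06,t1,50,0,27,5.4000000000000004,92,11,2.4987654320987653,89,1.1000000000000001,0.5,0.69999999999999996,0.11,0.21000000000000002,0.31000000000000005,0.41000000000000003,0.51000000000000001,0.6100000000000001,0.71000000000000008,0.81000000000000005,0.91000000000000003,1.01,1.1100000000000001
S07,t1,50,0,27,5.4000000000000004,92,75,17.037037037037038,89,1.1000000000000001,0.5,0.69999999999999996,0.11,0.21000000000000002,0.31000000000000005,0.41000000000000003,0.51000000000000001,0.6100000000000001,0.71000000000000008,0.81000000000000005,0.91000000000000003,1.01,1.1100000000000001
S08,t1,50,0,27,5.4000000000000004,92,11,2.4987654320987653,89,1.1000000000000001,0.5,0.69999999999999996,0.11,0.21000000000000002,0.31000000000000005,,0.51000000000000001,0.6100000000000001,0.71000000000000008,0.81000000000000005,0.91000000000000003,1.01,1.1100000000000001
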