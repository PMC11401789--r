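species,locus,equation_id,n,mean_kg
Protaceratherium minutum,m1,legendre_m1,19,508.93
Protaceratherium minutum,m1,janis_m1,19,685.34
Protaceratherium minutum,m2,janis_m2,16,496.03
Protaceratherium minutum,m2,damuth_m2,16,438.11
Protaceratherium minutum,M1,fk_M1,10,474.28
Protaceratherium minutum,M2,janis_M2,9,644.10
Protaceratherium minutum,M2,damuth_M2,9,532.53
Protaceratherium minutum,M2,fk_M2,9,487.95
Mesaceratherium paulhiacense,m1,legendre_m1,4,1389.20
Mesaceratherium paulhiacense,m1,janis_m1,4,2043.93
Mesaceratherium paulhiacense,m2,janis_m2,7,2022.79
Mesaceratherium paulhiacense,m2,damuth_m2,7,1687.06
Mesaceratherium paulhiacense,M1,fk_M1,6,1935.42
Mesaceratherium paulhiacense,M2,janis_M2,7,2327.43
Mesaceratherium paulhiacense,M2,damuth_M2,7,1811.66
Mesaceratherium paulhiacense,M2,fk_M2,7,1700.52
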