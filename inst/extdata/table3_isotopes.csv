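specimen_id,weight_mg,tooth,species,d13C_vpdb,d13C_sd,d18O_vpdb,d18O_sd
47950,628,M3,Protaceratherium minutum,-7.47,0.01,-5.34,0.04
48079,520,M3,Protaceratherium minutum,-8.25,0.02,-5.2,0.03
48184,580,M3,Protaceratherium minutum,-8.51,0.04,-4.78,0.06
48072,628,m3,Mesaceratherium paulhiacense,-9.06,0.02,-5.15,0.04
48008,722,M1,Mesaceratherium paulhiacense,-10.77,0.02,-5.32,0.03
48183,502,P4,Mesaceratherium paulhiacense,-12.76,0.01,-6.04,0.02
47877,1054,M3,Mesaceratherium paulhiacense,-11.01,0.02,-5.29,0.02
47877,554,M1-2,Mesaceratherium paulhiacense,-9.47,0.01,-5.01,0.02
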