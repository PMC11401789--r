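"id","locus","predictor","log_base","slope","intercept","length_divisor","output_unit","source"
"legendre_m1","m1","length_width","ln",1.5133,3.6515,1,"g","Legendre 1986"
"janis_m1","m1","length","log10",3.26,1.337,10,"kg","Janis 1990"
"janis_m2","m2","length","log10",3.2,1.13,10,"kg","Janis 1990"
"damuth_m2","m2","length","log10",3.07,1.07,1,"g","Damuth 1990"
"fk_M1","M1","length","ln",3.19,2.1,1,"g","Fortelius & Kappelman 1993"
"janis_M2","M2","length","log10",3.18,1.091,10,"kg","Janis 1990"
"damuth_M2","M2","length","log10",3.03,1.06,1,"g","Damuth 1990"
"fk_M2","M2","length","ln",3.09,2.14,1,"g","Fortelius & Kappelman 1993"
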