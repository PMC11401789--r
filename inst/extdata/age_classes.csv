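"class_id","index","start_years","end_years","provenance"
"0",0,0,0.125,"anchored"
"I",1,0.125,0.229166666666667,"interpolated"
"II",2,0.229166666666667,0.333333333333333,"interpolated"
"III",3,0.333333333333333,1,"anchored"
"IV",4,1,1.5,"anchored"
"V",5,1.5,3,"anchored"
"VI",6,3,3.5,"interpolated"
"VII",7,3.5,4,"interpolated"
"VIII",8,4,7,"anchored"
"IX",9,7,9,"anchored"
"X",10,9,11,"anchored"
"XI",11,11,15,"interpolated"
"XII",12,15,20,"interpolated"
"XIII",13,20,25,"interpolated"
"XIV",14,25,30,"interpolated"
"XV",15,30,35,"interpolated"
"XVI",16,35,40,"interpolated"
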