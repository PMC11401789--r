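"locus","wear_stage","age_classes"
"d1",1,"0"
"d1",2,"I"
"d1",3,"I"
"d1",4,"II"
"d1",5,"III"
"d1",6,"IV"
"d1",7,"IV"
"d1",8,"V"
"d1",9,"VI"
"d1",10,"VI"
"d2",1,"0"
"d2",2,"I"
"d2",3,"I"
"d2",4,"II"
"d2",5,"III"
"d2",6,"IV"
"d2",7,"IV"
"d2",8,"V"
"d2",9,"VI"
"d2",10,"VI"
"d3",1,"0"
"d3",2,"I"
"d3",3,"II"
"d3",4,"II"
"d3",5,"III"
"d3",6,"IV"
"d3",7,"V"
"d3",8,"VI"
"d3",9,"VI"
"d3",10,"VII"
"d4",1,"I"
"d4",2,"II"
"d4",3,"II"
"d4",4,"III"
"d4",5,"IV"
"d4",6,"V"
"d4",7,"V"
"d4",8,"VI"
"d4",9,"VII"
"d4",10,"VII"
"D1",1,"0"
"D1",2,"I"
"D1",3,"I"
"D1",4,"II"
"D1",5,"III"
"D1",6,"IV"
"D1",7,"IV"
"D1",8,"V"
"D1",9,"VI"
"D1",10,"VI"
"D2",1,"0"
"D2",2,"I"
"D2",3,"I"
"D2",4,"II"
"D2",5,"III"
"D2",6,"IV"
"D2",7,"IV"
"D2",8,"V"
"D2",9,"VI"
"D2",10,"VI"
"D3",1,"0"
"D3",2,"I"
"D3",3,"II"
"D3",4,"II"
"D3",5,"III"
"D3",6,"IV"
"D3",7,"V"
"D3",8,"VI"
"D3",9,"VI"
"D3",10,"VII"
"D4",1,"I"
"D4",2,"II"
"D4",3,"II"
"D4",4,"III"
"D4",5,"IV"
"D4",6,"V"
"D4",7,"V"
"D4",8,"VI"
"D4",9,"VII"
"D4",10,"VII"
"p2",1,"VI"
"p2",2,"VII"
"p2",3,"VIII"
"p2",4,"IX"
"p2",5,"X;XI"
"p2",6,"XII"
"p2",7,"XIII"
"p2",8,"XIV"
"p2",9,"XV"
"p2",10,"XVI"
"p3",1,"VI"
"p3",2,"VII"
"p3",3,"VIII"
"p3",4,"IX"
"p3",5,"X;XI"
"p3",6,"XII"
"p3",7,"XIII"
"p3",8,"XIV"
"p3",9,"XV"
"p3",10,"XVI"
"p4",1,"VII"
"p4",2,"VIII"
"p4",3,"IX"
"p4",4,"X"
"p4",5,"XI"
"p4",6,"XII"
"p4",7,"XIII"
"p4",8,"XIV"
"p4",9,"XV"
"p4",10,"XVI"
"P2",1,"VI"
"P2",2,"VII"
"P2",3,"VIII"
"P2",4,"IX"
"P2",5,"X;XI"
"P2",6,"XII"
"P2",7,"XIII"
"P2",8,"XIV"
"P2",9,"XV"
"P2",10,"XVI"
"P3",1,"VI"
"P3",2,"VII"
"P3",3,"VIII"
"P3",4,"IX"
"P3",5,"X;XI"
"P3",6,"XII"
"P3",7,"XIII"
"P3",8,"XIV"
"P3",9,"XV"
"P3",10,"XVI"
"P4",1,"VII"
"P4",2,"VIII"
"P4",3,"IX"
"P4",4,"X"
"P4",5,"XI"
"P4",6,"XII"
"P4",7,"XIII"
"P4",8,"XIV"
"P4",9,"XV"
"P4",10,"XVI"
"m1",1,"VI"
"m1",2,"VII"
"m1",3,"VIII"
"m1",4,"IX"
"m1",5,"X;XI"
"m1",6,"XII"
"m1",7,"XIII"
"m1",8,"XIV"
"m1",9,"XV"
"m1",10,"XVI"
"m2",1,"VII"
"m2",2,"VIII"
"m2",3,"IX"
"m2",4,"X"
"m2",5,"XI"
"m2",6,"XII"
"m2",7,"XIII"
"m2",8,"XIV"
"m2",9,"XV"
"m2",10,"XVI"
"m3",1,"VIII"
"m3",2,"IX"
"m3",3,"X"
"m3",4,"XI"
"m3",5,"XII"
"m3",6,"XII"
"m3",7,"XIII"
"m3",8,"XIV"
"m3",9,"XV"
"m3",10,"XVI"
"M1",1,"VI"
"M1",2,"VII"
"M1",3,"VIII"
"M1",4,"IX"
"M1",5,"X;XI"
"M1",6,"XII"
"M1",7,"XIII"
"M1",8,"XIV"
"M1",9,"XV"
"M1",10,"XVI"
"M2",1,"VII"
"M2",2,"VIII"
"M2",3,"IX"
"M2",4,"X"
"M2",5,"XI"
"M2",6,"XII"
"M2",7,"XIII"
"M2",8,"XIV"
"M2",9,"XV"
"M2",10,"XVI"
"M3",1,"VIII"
"M3",2,"IX"
"M3",3,"X"
"M3",4,"XI"
"M3",5,"XII"
"M3",6,"XII"
"M3",7,"XIII"
"M3",8,"XIV"
"M3",9,"XV"
"M3",10,"XVI"
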