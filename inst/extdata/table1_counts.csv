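method,n_minutum,n_paulhiacense
mesowear,16,12
microwear_grinding,21,11
microwear_shearing,9,5
enamel_hypoplasia,317,149
body_mass,54,24
stable_isotopes,3,5
mortality_curves,336,155
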