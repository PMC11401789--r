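# Ulm-Westtangente locality (Lower Freshwater Molasse, Baden-Wuerttemberg
# Basin, Germany; Aquitanian, MN2a). Coordinates converted from the original
# Gauss-Krueger survey values; altitude in m above sea level.
latitude_deg: 48.418321
longitude_deg: 9.933701
altitude_m: 590
# atmospheric delta-13C of CO2, permil VPDB: reconstructed for ~22 Mya
# (benthic foraminifera) and the post-1930 modern reference
d13C_atm_paleo: -6.1
d13C_atm_modern: -8
lifespan_years: 40
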