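group,mp_ratio,gene,minor_allele_pct
in_vitro,0.016,IGF2,2.9
in_vitro,0.020,IGF2,6.9
in_vitro,0.023,IGF2,7.0
in_vitro,0.027,IGF2,1.6
in_vitro,0.032,IGF2,15.8
in_vitro,0.055,H19,2.5
in_vitro,0.058,H19,1.9
in_vitro,0.068,H19,1.2
in_vitro,0.156,H19,1.6
in_vitro,0.184,H19,1.0
in_vitro,0.472,H19,0.8
in_vivo,0.004,IGF2,2.8
in_vivo,0.027,IGF2,2.6
in_vivo,0.088,H19,3.0
in_vivo,0.187,H19,2.1
in_vivo,0.236,IGF2,5.5
in_vivo,0.307,IGF2,8.8
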