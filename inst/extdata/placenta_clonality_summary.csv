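assay,tissue_class,group,n_individuals,n_sections,mean,dispersion,dispersion_type,p
XI,placenta,in_vitro,50,5,0.4775,0.1637,sd,0.5
XI,placenta,in_vivo,54,5,0.4824,0.1502,sd,0.5
MP,placenta,in_vitro,45,5,0.1017,0.0111,variance,0.1
MP,placenta,in_vivo,56,5,0.0801,0.0091,variance,0.1
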