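name,molecular_weight_g_mol,vapor_pressure_pa,density_g_cm3,diffusion_coefficient_cm2_s,article_concentration_g_cm3
synthetic_vvoc,72,24000,0.79,,
synthetic_voc,136,192,0.84,,
synthetic_ivoc,170,5,0.9,,
synthetic_svoc_plasticizer,390,2.5e-5,0.98,1e-12,0.13
synthetic_lowvol,250,0.05,1.1,1e-10,0.05
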