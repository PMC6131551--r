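material,n,rho_kg_m3,velocity_m_s
water,1.330,998,1482
cytoplasm,1.375,1050,NA
nucleus,1.360,1060,NA
nucleolus,1.380,1100,NA
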