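protein,band_ratio,control_mass_pg,lysate_fraction_loaded
Cdc42,1.375,106.5,0.002018
Rac1,3.549,22.5,0.002018
RhoA,1.250,106.5,0.002018
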