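site,thickness_mm,quantity,value,units,provenance,source
scalp,5,attenuation_percent,3.78,percent,simulation,published uniform-thickness tissue table
skull,5,attenuation_percent,85.45,percent,simulation,published uniform-thickness tissue table
brain,5,attenuation_percent,5.54,percent,simulation,published uniform-thickness tissue table
scalp,5,peak_pressure,2.19,MPa,simulation,published uniform-thickness tissue table
skull,5,peak_pressure,0.382,MPa,simulation,published uniform-thickness tissue table
brain,5,peak_pressure,2.15,MPa,simulation,published uniform-thickness tissue table
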