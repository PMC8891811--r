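site,thickness_mm,quantity,value,units,provenance,source
scalp,3.35,attenuation_percent,3.21,percent,simulation,published single-layer tissue comparison
skull,5,attenuation_percent,83.22,percent,simulation,published single-layer tissue comparison
brain,40,attenuation_percent,34.49,percent,simulation,published single-layer tissue comparison
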