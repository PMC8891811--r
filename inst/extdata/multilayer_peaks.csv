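site,thickness_mm,quantity,value,units,provenance,source
water,NA,peak_pressure,2.276,MPa,simulation,published multilayer comparison
water,NA,peak_pressure,2.276,MPa,phantom,published multilayer comparison
multilayer,NA,peak_pressure,0.219,MPa,simulation,published multilayer comparison
multilayer,NA,peak_pressure,0.255,MPa,phantom,published multilayer comparison
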