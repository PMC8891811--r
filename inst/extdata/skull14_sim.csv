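site,thickness_mm,quantity,value,units,provenance,source
S1,3.5,attenuation_percent,75.52,percent,simulation,published skull-14 site comparison
S2,4.5,attenuation_percent,79.85,percent,simulation,published skull-14 site comparison
S3,5,attenuation_percent,82.96,percent,simulation,published skull-14 site comparison
S4,6.5,attenuation_percent,88,percent,simulation,published skull-14 site comparison
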