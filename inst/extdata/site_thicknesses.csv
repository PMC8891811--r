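site,thickness_mm,quantity,value,units,provenance,source
S1,3.5,skull_thickness,3.5,mm,phantom,published test-point thicknesses
S2,4.5,skull_thickness,4.5,mm,phantom,published test-point thicknesses
S3,5,skull_thickness,5,mm,phantom,published test-point thicknesses
S4,6.5,skull_thickness,6.5,mm,phantom,published test-point thicknesses
S5,7.1,skull_thickness,7.1,mm,phantom,published test-point thicknesses
S6,7.1,skull_thickness,7.1,mm,phantom,published test-point thicknesses
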