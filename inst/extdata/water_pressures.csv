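site,thickness_mm,quantity,value,units,provenance,source
100V,NA,water_peak_pressure,0.862,MPa,phantom,published water-tank calibration
200V,NA,water_peak_pressure,1.931,MPa,phantom,published water-tank calibration
300V,NA,water_peak_pressure,2.138,MPa,phantom,published water-tank calibration
400V,NA,water_peak_pressure,2.276,MPa,phantom,published water-tank calibration
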