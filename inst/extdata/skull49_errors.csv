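site,thickness_mm,quantity,value,units,provenance,source
S5,7.1,model_relative_error_percent,1.99,percent,phantom,published skull-49 site comparison
S6,7.1,model_relative_error_percent,2.44,percent,phantom,published skull-49 site comparison
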