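gene_id,e1,e2,e3,e4
gA,10,12,8,15
gB,130,125,128,133
gC,250,255,245,248
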