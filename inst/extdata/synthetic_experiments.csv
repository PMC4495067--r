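experiment_id,group_id,kappa
e1,sp1,40
e2,sp1,30
e3,sp2,35
e4,sp2,25
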