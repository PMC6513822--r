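zone_code,white,mixed,black,other
E08000002,134004,804,1106,8344
E08000003,281654,5336,22105,55454
E08000004,139659,1405,803,28392
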