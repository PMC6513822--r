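zone_code,unemployed,not-unemployed
E08000002,5032,139226
E08000003,20375,344174
E08000004,8416,161843
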