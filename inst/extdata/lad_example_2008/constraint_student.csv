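zone_code,student,not-student
E08000002,5745,138513
E08000003,22054,342495
E08000004,8115,162144
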