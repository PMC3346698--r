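P023	1
P024	2
P006	2
P029	2
P012	3
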