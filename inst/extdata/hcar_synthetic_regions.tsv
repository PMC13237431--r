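name	start	end
TM1	12	40
TM2	66	88
TM3	95	125
TM4	130	155
TM5	185	215
TM6	230	260
TM7	270	295
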